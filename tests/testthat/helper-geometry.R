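# geometric fixtures built in code

cube_mesh <- function(edge = 15, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(c(0, edge), c(0, edge), c(0, edge)))
  v <- sweep(v, 2, origin, "+")
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  m <- tri_mesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

uv_sphere <- function(radius = 10, centre = c(0, 0, 0), n_theta = 48,
                      n_phi = 24) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ph <- seq(0, pi, length.out = n_phi + 1)[c(-1, -(n_phi + 1))]
  ring <- function(p) cbind(radius * sin(p) * cos(th),
                            radius * sin(p) * sin(th),
                            radius * cos(p))
  v <- do.call(rbind, lapply(ph, ring))
  np <- length(ph)
  top <- nrow(v) + 1L
  bot <- nrow(v) + 2L
  v <- rbind(v, c(0, 0, radius), c(0, 0, -radius))
  v <- sweep(v, 2, centre, "+")
  faces <- NULL
  nxt <- c(2:n_theta, 1)
  for (i in seq_len(np - 1)) {
    a <- (i - 1) * n_theta + seq_len(n_theta)
    b <- a[nxt]
    c3 <- i * n_theta + seq_len(n_theta)
    d <- c3[nxt]
    faces <- rbind(faces, cbind(a, d, b), cbind(a, c3, d))
  }
  first <- seq_len(n_theta)
  last <- (np - 1) * n_theta + seq_len(n_theta)
  faces <- rbind(faces, cbind(top, first, first[nxt]),
                 cbind(bot, last[nxt], last))
  m <- tri_mesh(v, faces)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotation_xyz <- function(ax, ay, az) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}
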