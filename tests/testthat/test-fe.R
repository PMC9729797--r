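# FE core: assembly, solver, stress/strain measures

test_that("assembled stiffness is symmetric and springs add rank-1 blocks", {
  cm <- make_cantilever_benchmark(100, 2, 110000, n_elems = 8)
  asm <- fe_assemble(cm)
  K <- asm$K
  expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-12)

  # grounded spring at the tip, oblique direction
  d <- c(1, 2, 2) / 3
  cm2 <- cm
  cm2$springs <- data.frame(kind = "beam", node = 9L, dx = d[1], dy = d[2],
                            dz = d[3], k = 123.4)
  asm2 <- fe_assemble(cm2)
  dK <- asm2$K - asm$K
  tdof <- asm$beam_tdof[9, ]
  blk <- as.matrix(dK[tdof, tdof])
  expect_equal(blk, 123.4 * outer(d, d), tolerance = 1e-10)
  expect_equal(sum(abs(dK)) , sum(abs(blk)), tolerance = 1e-10)
  # diagonal entry in the spring's local frame increases by exactly k
  expect_equal(as.numeric(t(d) %*% blk %*% d), 123.4, tolerance = 1e-10)
})

test_that("sparse solution matches a dense solve on a small model", {
  pm <- make_patch_test(2, 12000, 0.3, strain = c(1e-3, 2e-4, 0, 5e-4, 0, 0))
  asm <- fe_assemble(pm)
  expect_lte(asm$ndof, 300)
  res <- fe_solve(asm)
  free <- setdiff(seq_len(asm$ndof), asm$bc_dof)
  u <- numeric(asm$ndof)
  u[asm$bc_dof] <- asm$bc_val
  rhs <- asm$f[free] -
    as.numeric(asm$K[free, asm$bc_dof, drop = FALSE] %*% asm$bc_val)
  u[free] <- solve(as.matrix(asm$K[free, free]), rhs)
  expect_lt(max(abs(u - res$u)) / max(abs(u)), 1e-9)
})

test_that("solver linearity, equilibrium residual and reaction balance", {
  cm <- make_cantilever_benchmark(80, 2, 100000, n_elems = 10, tip_load = 1)
  res1 <- fe_solve(fe_assemble(cm))
  cm$loads$fz <- cm$loads$fz * 2
  res2 <- fe_solve(fe_assemble(cm))
  expect_lt(max(abs(res2$u - 2 * res1$u)) / max(abs(res2$u)), 1e-10)
  expect_lt(res1$residual, 1e-8)
  # reactions at the clamp balance the applied load (no springs here)
  expect_equal(sum(res1$reactions[3]), 1, tolerance = 1e-6)  # z reaction
})

test_that("reciprocity: u_j(load at i) equals u_i(load at j)", {
  cm <- make_cantilever_benchmark(60, 2, 50000, n_elems = 12, tip_load = 0)
  asm0 <- fe_assemble(cm)
  load_at <- function(node) {
    m <- cm
    m$loads <- data.frame(kind = "beam", node = node, fx = 0, fy = 0, fz = -1)
    fe_solve(fe_assemble(m))
  }
  ri <- load_at(5L)
  rj <- load_at(11L)
  uji <- ri$u[asm0$beam_tdof[11, 3]]
  uij <- rj$u[asm0$beam_tdof[5, 3]]
  expect_equal(uji, uij, tolerance = 1e-9)
})

test_that("unconstrained model raises a singular-system diagnostic", {
  cm <- make_cantilever_benchmark(60, 2, 50000, n_elems = 4)
  cm$bcs <- NULL
  # CHOLMOD also emits a not-positive-definite warning before our error
  expect_error(suppressWarnings(fe_solve(fe_assemble(cm))),
               "singular|rigid-body")
})

test_that("untied floating strut node is an assembly error naming the node", {
  pm <- make_patch_test(2, 1000, 0.3)
  fem <- fe_model(vox = pm$vox,
                  beam_nodes = rbind(c(0.5, 0.5, 0.5), c(50, 50, 50)),
                  beam_elems = data.frame(a = 1, b = 2, diameter = 0.5,
                                          mat = "patch", tag = "trabecular"),
                  materials = pm$materials, bcs = pm$bcs)
  expect_error(fe_assemble(fem), "untied floating strut node.*2")
})

test_that("von-Mises stress: closed forms and rotational invariance", {
  expect_equal(von_mises(diag(c(100, 0, 0))), 100)
  expect_equal(von_mises(diag(c(7, 7, 7))), 0)
  tau <- 10
  s <- matrix(c(0, tau, 0, tau, 0, 0, 0, 0, 0), 3)
  expect_equal(von_mises(s), tau * sqrt(3))
  set.seed(99)
  sig <- matrix(rnorm(9), 3); sig <- sig + t(sig)
  v0 <- von_mises(sig)
  for (i in 1:100) {
    R <- rotation_xyz(runif(1, 0, 2 * pi), runif(1, 0, pi), runif(1, 0, 2 * pi))
    expect_equal(von_mises(R %*% sig %*% t(R)), v0, tolerance = 1e-9)
  }
  expect_error(von_mises(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3)),
               class = "scaffem_invalid_parameter")
})

test_that("equivalent strain: deviatoric measure, brute-force oracle,
           homogeneity", {
  # uniaxial stress state, nu = 0.3: oracle via principal deviatoric strains
  eps <- diag(c(1000, -300, -300)) * 1e-6
  ev <- eigen(eps, symmetric = TRUE)$values
  em <- mean(ev)
  oracle <- sqrt(2 / 3 * sum((ev - em)^2)) * 1e6
  expect_equal(equivalent_strain(eps), oracle, tolerance = 1e-12)
  expect_equal(oracle, (2 / 3) * (1 + 0.3) * 1000, tolerance = 1e-9)
  expect_equal(equivalent_strain(diag(c(5e-4, 5e-4, 5e-4))), 0)
  set.seed(5)
  e6 <- rnorm(6) * 1e-3
  expect_equal(equivalent_strain(2 * e6), 2 * equivalent_strain(e6),
               tolerance = 1e-12)
  # engineering-shear vector form consistent with the tensor form
  g <- 1e-3
  expect_equal(equivalent_strain(c(0, 0, 0, g, 0, 0)),
               equivalent_strain(matrix(c(0, g / 2, 0, g / 2, 0, 0, 0, 0, 0), 3)))
})

test_that("beam surface-fiber stress: closed forms and angular-sampling
           oracle", {
  d <- 2
  A <- pi * d^2 / 4
  expect_equal(beam_equivalent_stress(d, N = 100), 100 / A)
  M <- 50
  expect_equal(beam_equivalent_stress(d, 0, 0, My = M), 32 * M / (pi * d^3))
  # mixed case vs brute-force maximization over 360 circumferential angles
  N <- 80; Ty <- 30; My <- 20; Mz <- -45
  I <- pi * d^4 / 64; J <- 2 * I; c <- d / 2
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  sig <- N / A + (My * sin(th) - Mz * cos(th)) * c / I
  tau <- Ty * c / J
  oracle <- max(sqrt(sig^2 + 3 * tau^2))
  expect_equal(beam_equivalent_stress(d, N, Ty, My, Mz), oracle,
               tolerance = 5e-3)
  expect_error(beam_equivalent_stress(0, 1), class = "scaffem_invalid_parameter")
})
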