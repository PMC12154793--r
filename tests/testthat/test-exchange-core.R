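# Exchange matrices, eigenstructure, and the matrix-exponential simulator.

test_that("constructed exchange matrices conserve magnetization and obey detailed balance", {
  set.seed(101)
  for (rep in 1:25) {
    f3 <- as.numeric(prop.table(runif(3, 0.05, 1)))
    kt <- runif(1, 10, 500); kg <- runif(1, 1, 100)
    K3 <- build_exchange_matrix(exchange_three_site(kt, kg), f3)
    expect_lt(max(abs(colSums(K3))), 1e-10 * kt)
    expect_lt(max(abs(K3 %*% f3)), 1e-10 * kt)
    # detailed balance: flux i->j equals flux j->i; rate j->i is -K[i, j]
    for (i in 1:3) for (j in 1:3) if (i != j) {
      expect_equal((-K3[j, i]) * f3[i], (-K3[i, j]) * f3[j],
                   tolerance = 1e-10)
    }
    f2 <- as.numeric(prop.table(runif(2, 0.05, 1)))
    K2 <- build_exchange_matrix(exchange_two_site(kt), f2)
    expect_lt(max(abs(colSums(K2))), 1e-10 * kt)
    expect_equal((-K2[2, 1]) * f2[1], (-K2[1, 2]) * f2[2], tolerance = 1e-10)
  }
})

test_that("two-site matrix takes its closed form and eigenvalues (0, k)", {
  K <- build_exchange_matrix(exchange_two_site(300), c(0.5, 0.5))
  expect_equal(K, 300 * rbind(c(0.5, -0.5), c(-0.5, 0.5)))
  for (fa in c(0.1, 0.37, 0.8)) {
    K <- build_exchange_matrix(exchange_two_site(120), c(fa, 1 - fa))
    ev <- sort(eigen(K, only.values = TRUE)$values)
    expect_equal(ev, c(0, 120), tolerance = 1e-9)
    expect_equal(exchange_eigenvalues(exchange_two_site(120), c(fa, 1 - fa)),
                 c(0, 120))
  }
})

test_that("three-site closed-form eigenvalues match a numerical eigensolver", {
  set.seed(202)
  for (rep in 1:100) {
    f <- as.numeric(prop.table(runif(3, 0.02, 1)))
    kt <- runif(1, 5, 600); kg <- runif(1, 0.5, 200)
    spec <- exchange_three_site(kt, kg)
    lam <- exchange_eigenvalues(spec, f)
    num <- sort(Re(eigen(build_exchange_matrix(spec, f),
                         only.values = TRUE)$values))
    expect_equal(sort(lam), num, tolerance = 1e-9)
    expect_equal(lam[3], kt)
    expect_equal(lam[2], f[1] * kt + (f[2] + f[3]) * kg, tolerance = 1e-12)
  }
  # slow-mode anchor: fa = 0.315, equal ICS split, (300, 30) -> 115 1/s
  lam <- exchange_eigenvalues(exchange_three_site(300, 30),
                              c(0.315, 0.3425, 0.3425))
  expect_equal(lam[2], 115, tolerance = 0.001)
})

test_that("with no ECS the three-site system reduces to two-site b-c exchange", {
  f <- c(0, 0.6, 0.4)
  K3 <- build_exchange_matrix(exchange_three_site(300, 30), f)
  # no flux enters site a, and site a holds zero magnetization
  expect_equal(K3[1, 2:3], c(0, 0))
  expect_lt(max(abs(K3 %*% f)), 1e-12)
  K2 <- build_exchange_matrix(exchange_two_site(30), c(0.6, 0.4))
  expect_equal(K3[2:3, 2:3], K2, tolerance = 1e-12)
  expect_equal(exchange_eigenvalues(exchange_three_site(300, 30), f)[2], 30)
})

test_that("general-mode exchange matrices are validated", {
  K <- matrix(c(10, -10, -5, 5), 2, 2)
  expect_silent(exchange_general(K))
  expect_error(exchange_general(matrix(c(10, -9, -5, 5), 2, 2)), "sum to 0")
})

test_that("mixing operator conserves magnetization and forms a semigroup", {
  set.seed(303)
  for (rep in 1:20) {
    f <- as.numeric(prop.table(runif(3, 0.05, 1)))
    K <- build_exchange_matrix(
      exchange_three_site(runif(1, 10, 400), runif(1, 1, 80)), f)
    S0 <- runif(3)
    t1 <- runif(1, 0.001, 0.1); t2 <- runif(1, 0.001, 0.1)
    E1 <- as.matrix(Matrix::expm(-t1 * K))
    E2 <- as.matrix(Matrix::expm(-t2 * K))
    E12 <- as.matrix(Matrix::expm(-(t1 + t2) * K))
    expect_equal(sum(E1 %*% S0), sum(S0), tolerance = 1e-10)
    expect_equal(E1 %*% E2, E12, tolerance = 1e-9)
  }
})

test_that("simulated signals satisfy conservation and no-mixing limits", {
  sys <- compartment_system(c(0.3, 0.3, 0.4), ADC = c(1, 0.7, 0.1), R1 = 0)
  tm <- c(0.2, 1, 5, 20, 100)
  # b1 = b2 = 0 and R1 = 0: total magnetization 1 at every tm
  prot0 <- dexsy_protocol(list(sgse_encoding(0, 0)), tm)
  s0 <- simulate_dexsy(sys, ref_spec_3xm(), prot0)
  expect_equal(s0$signal, rep(1, length(tm)), tolerance = 1e-12)
  # K = 0 (general mode), R1 = 0, equal b: mixture attenuation, flat in tm
  protb <- dexsy_protocol(list(sgse_encoding(0.5, 0.5)), tm)
  b <- b_value(0.5, 15.3)
  sK0 <- simulate_dexsy(sys, exchange_general(matrix(0, 3, 3)), protb)
  expect_equal(sK0$signal,
               rep(sum(sys$f * exp(-2 * b * sys$ADC)), length(tm)),
               tolerance = 1e-12)
  # with exchange on and R1 = 0, equal-b signal is non-increasing in tm
  sx <- simulate_dexsy(sys, ref_spec_3xm(), protb)
  expect_true(all(diff(sx$signal) <= 1e-12))
  expect_true(all(sx$signal > 0))
})

test_that("encoding-period exchange and R2 terms engage only when requested", {
  sys <- compartment_system(c(0.4, 0.3, 0.3), ADC = c(1, 1, 0.1),
                            R1 = 1, R2 = 20)
  prot <- ref_protocol()
  base <- simulate_dexsy(sys, ref_spec_3xm(), prot)
  full <- simulate_dexsy(sys, ref_spec_3xm(), prot,
                         include_encoding_exchange = TRUE, include_R2 = TRUE)
  expect_false(isTRUE(all.equal(base$signal, full$signal)))
  # R2 decay over 2(tau1 + tau2) can only reduce the signal
  expect_true(all(full$signal < base$signal))
})

test_that("fraction-weighted ADC prediction follows its algebra", {
  expect_equal(predict_adc(compartment_system(c(1, 0), c(1, 0.5), 0)), 1)
  f <- c(0.32, 0.34, 0.34)
  expect_equal(predict_adc(compartment_system(f, c(1, 1, 0.1), 0)),
               0.55 + 0.45 * 0.32, tolerance = 1e-12)
  expect_equal(predict_adc(compartment_system(rep(1 / 3, 3), c(1, 1, 1), 0)), 1)
})

test_that("particle oracle is reproducible and recovers exact limits", {
  sys <- compartment_system(c(0.4, 0.6), ADC = c(1, 0.1), R1 = 1)
  prot <- dexsy_protocol(list(sgse_encoding(0.593, 0.580)), c(1, 10, 100))
  # K = 0: exact mixture attenuation within 3 SE
  o0 <- ctmc_oracle(sys, exchange_general(matrix(0, 2, 2)), prot,
                    n_particles = 2e4, seed = 5)
  exact <- simulate_dexsy(sys, exchange_general(matrix(0, 2, 2)), prot)
  expect_true(all(abs(o0$signal - exact$signal) <= 3 * o0$se))
  # two-site exchange: matches the matrix-exponential signal within 3 SE
  o1 <- ctmc_oracle(sys, exchange_two_site(300), prot,
                    n_particles = 5e4, seed = 5)
  m1 <- simulate_dexsy(sys, exchange_two_site(300), prot)
  expect_true(all(abs(o1$signal - m1$signal) <= 3 * o1$se))
  # fixed seed -> bitwise identical rerun
  o2 <- ctmc_oracle(sys, exchange_two_site(300), prot,
                    n_particles = 5e4, seed = 5)
  expect_identical(o1, o2)
})

test_that("system and protocol constructors validate their inputs", {
  expect_error(compartment_system(c(0.5, 0.6), c(1, 1)), "sum to 1")
  expect_error(compartment_system(c(0.5, 0.5), c(1, -1)), ">= 0")
  expect_error(dexsy_protocol(list(sgse_encoding(0.2, 0.7)), c(5, 1)),
               "increasing")
  expect_error(exchange_three_site(-1, 30), ">= 0")
  enc <- sgse_encoding(0.200, 0.735, g = 15.3)
  expect_equal(enc$b1, b_value(0.200, 15.3))
  expect_equal(enc$b2, b_value(0.735, 15.3))
})
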