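# N-site exchange matrices and SGSE-DEXSY signal simulation.
#
# Sign convention: the exchange matrix K has positive diagonals (total exit
# rate from each site) and negative off-diagonals; K[i, j] = -(rate j -> i),
# so every column of K sums to zero and total magnetization is conserved.
# Sites are ordered (a, b, c) = (ECS, mobile ICS, restricted ICS).

#' Compartment system for exchange simulation
#'
#' Describes the exchanging water environments: their signal fractions,
#' apparent diffusivities, and relaxation rates.
#'
#' @param f Site signal fractions; non-negative, summing to 1.
#' @param ADC Per-site apparent diffusion coefficients in um^2/ms (>= 0).
#' @param R1 Per-site spin-lattice relaxation rates in 1/s (scalar recycled).
#' @param R2 Per-site spin-spin relaxation rates in 1/s (scalar recycled,
#'   default 0; only used when encoding-period relaxation is enabled).
#' @param labels Optional site names; defaults to letters a, b, c, ...
#' @return An object of class `compartment_system`.
#' @examples
#' compartment_system(f = c(0.32, 0.34, 0.34), ADC = c(1, 1, 0.1), R1 = 1)
#' @export
compartment_system <- function(f, ADC, R1 = 0, R2 = 0, labels = NULL) {
  n <- length(f)
  if (n < 2) stop("need at least two sites")
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop("`f` must be non-negative and sum to 1")
  if (length(ADC) != n) stop("`ADC` must have one value per site")
  if (any(ADC < 0)) stop("`ADC` must be >= 0")
  R1 <- rep_len(R1, n); R2 <- rep_len(R2, n)
  if (any(R1 < 0) || any(R2 < 0)) stop("relaxation rates must be >= 0")
  if (is.null(labels)) labels <- letters[seq_len(n)]
  structure(list(f = as.numeric(f), ADC = as.numeric(ADC),
                 R1 = R1, R2 = R2, labels = labels, n_sites = n),
            class = "compartment_system")
}

#' Three-site gray-matter system from an ECS fraction
#'
#' Builds the standard three-site system with sites
#' (a, b, c) = (ECS, mobile ICS, restricted ICS). The two ICS fractions
#' split the intracellular signal equally by default.
#'
#' @param fa ECS signal fraction in [0, 1].
#' @param ADC Per-site diffusivities, default c(1, 1, 0.1) um^2/ms.
#' @param R1 Spin-lattice rate(s), default 1 s^-1 for all sites.
#' @param bc_split Fraction of the ICS signal assigned to site b (default 0.5).
#' @return A [compartment_system()] with three sites.
#' @export
system_three_site <- function(fa, ADC = c(1, 1, 0.1), R1 = 1, bc_split = 0.5) {
  if (fa < 0 || fa > 1) stop("`fa` must lie in [0, 1]")
  if (bc_split < 0 || bc_split > 1) stop("`bc_split` must lie in [0, 1]")
  fb <- (1 - fa) * bc_split
  compartment_system(c(fa, fb, 1 - fa - fb), ADC, R1)
}

#' Two-site system from an ECS fraction
#'
#' @param fa ECS signal fraction in [0, 1].
#' @param ADC Per-site diffusivities, default c(1, 0.1) um^2/ms.
#' @param R1 Spin-lattice rate(s), default 1 s^-1.
#' @return A [compartment_system()] with two sites.
#' @export
system_two_site <- function(fa, ADC = c(1, 0.1), R1 = 1) {
  if (fa < 0 || fa > 1) stop("`fa` must lie in [0, 1]")
  compartment_system(c(fa, 1 - fa), ADC, R1)
}

#' Exchange specification
#'
#' `exchange_two_site(k)` specifies symmetric two-site exchange with total
#' rate constant k (the nonzero eigenvalue of K). `exchange_three_site(k_t,
#' k_g)` specifies the gray-matter topology: transmembrane exchange k_t
#' between ECS and both ICS sites (a-b, a-c), geometric exchange k_g between
#' the ICS sites (b-c). `exchange_general(K)` accepts a full rate matrix in
#' the package sign convention (columns must sum to zero).
#'
#' @param k,k_t,k_g Exchange rate constants in 1/s (>= 0).
#' @param K Full exchange matrix (1/s) for the general mode.
#' @return An object of class `exchange_spec`.
#' @examples
#' exchange_three_site(k_t = 300, k_g = 30)
#' @export
exchange_two_site <- function(k) {
  if (k < 0) stop("`k` must be >= 0")
  structure(list(mode = "two_site", k = k), class = "exchange_spec")
}

#' @rdname exchange_two_site
#' @export
exchange_three_site <- function(k_t, k_g) {
  if (k_t < 0 || k_g < 0) stop("rates must be >= 0")
  structure(list(mode = "three_site", k_t = k_t, k_g = k_g),
            class = "exchange_spec")
}

#' @rdname exchange_two_site
#' @export
exchange_general <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("`K` must be square")
  if (any(abs(colSums(K)) > 1e-8 * max(1, max(abs(K)))))
    stop("columns of `K` must sum to 0 (total magnetization balance)")
  structure(list(mode = "general", K = K), class = "exchange_spec")
}

#' Build the exchange matrix for a compartment system
#'
#' Constructs K (1/s) in the package sign convention. The two- and
#' three-site modes build K from the equilibrium fractions so that detailed
#' balance k_ij f_i = k_ji f_j holds for every site pair; the general mode
#' returns the user matrix after validation.
#'
#' @param spec An [exchange_two_site()], [exchange_three_site()] or
#'   [exchange_general()] object.
#' @param f Site fractions (ignored for the general mode).
#' @return The exchange matrix K; columns sum to zero, so K f = 0.
#' @examples
#' build_exchange_matrix(exchange_three_site(300, 30), c(0.32, 0.34, 0.34))
#' @export
build_exchange_matrix <- function(spec, f) {
  stopifnot(inherits(spec, "exchange_spec"))
  switch(spec$mode,
    two_site = {
      if (length(f) != 2) stop("two-site mode needs 2 fractions")
      fa <- f[1]; fb <- f[2]
      spec$k * rbind(c(fb, -fa),
                     c(-fb, fa))
    },
    three_site = {
      if (length(f) != 3) stop("three-site mode needs 3 fractions")
      fa <- f[1]; fb <- f[2]; fc <- f[3]
      kt <- spec$k_t; kg <- spec$k_g
      rbind(c((fb + fc) * kt, -fa * kt,           -fa * kt),
            c(-fb * kt,        fa * kt + fc * kg, -fb * kg),
            c(-fc * kt,       -fc * kg,            fa * kt + fb * kg))
    },
    general = spec$K
  )
}

#' Analytical exchange eigenvalues
#'
#' Eigenvalues of the exchange matrix in closed form. For the three-site
#' topology these are (0, fa k_t + (fb + fc) k_g, k_t): zero from total
#' balance, a slow mode mixing the two ICS sites through the ECS, and a fast
#' mode at the transmembrane rate. For two sites they are (0, k).
#'
#' @inheritParams build_exchange_matrix
#' @return Numeric vector of eigenvalues in 1/s, ascending.
#' @examples
#' exchange_eigenvalues(exchange_three_site(300, 30), c(0.315, 0.3425, 0.3425))
#' @export
exchange_eigenvalues <- function(spec, f) {
  stopifnot(inherits(spec, "exchange_spec"))
  switch(spec$mode,
    two_site = c(0, spec$k),
    three_site = {
      fa <- f[1]
      c(0, fa * spec$k_t + (1 - fa) * spec$k_g, spec$k_t)
    },
    general = sort(Re(eigen(spec$K, only.values = TRUE)$values))
  )
}

#' SGSE encoding pair
#'
#' A double diffusion encoding defined by the two half-echo times; the
#' b-values follow from the static-gradient relation [b_value()].
#'
#' @param tau1_ms,tau2_ms Half-echo times of the two encoding blocks, ms.
#' @param g Static gradient in T/m.
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1.
#' @return An object of class `sgse_encoding` with b1, b2 in ms/um^2.
#' @export
sgse_encoding <- function(tau1_ms, tau2_ms, g = 15.3,
                          gamma = nmr_constants()$gamma) {
  structure(list(tau1_ms = tau1_ms, tau2_ms = tau2_ms, g = g,
                 b1 = b_value(tau1_ms, g, gamma),
                 b2 = b_value(tau2_ms, g, gamma)),
            class = "sgse_encoding")
}

#' DEXSY acquisition protocol
#'
#' A set of SGSE encoding pairs acquired over a common mixing-time grid.
#'
#' @param encodings A list of [sgse_encoding()] objects.
#' @param tm_ms Mixing times in ms; non-negative and strictly increasing.
#' @return An object of class `dexsy_protocol`.
#' @export
dexsy_protocol <- function(encodings, tm_ms) {
  if (!all(vapply(encodings, inherits, TRUE, "sgse_encoding")))
    stop("`encodings` must be a list of sgse_encoding objects")
  if (any(tm_ms < 0) || any(diff(tm_ms) <= 0))
    stop("`tm_ms` must be non-negative and strictly increasing")
  structure(list(encodings = encodings, tm_ms = as.numeric(tm_ms)),
            class = "dexsy_protocol")
}

#' Reference DEXR protocol
#'
#' The two-encoding protocol used throughout the package: a diffusion-T1
#' reference pair (tau1, tau2) = (0.200, 0.735) ms (b ~ 0.089 and 4.435
#' ms/um^2 at g = 15.3 T/m) and an equal-b exchange-sensitive pair
#' (0.593, 0.580) ms (b ~ 2.329 and 2.179 ms/um^2), over mixing times
#' 0.2-300 ms.
#'
#' @param g Static gradient in T/m.
#' @param tm_ms Mixing-time grid in ms.
#' @return A [dexsy_protocol()].
#' @export
dexsy_protocol_default <- function(g = 15.3,
                                   tm_ms = c(0.2, 1, 2, 4, 7, 10, 20, 40,
                                             80, 160, 300)) {
  dexsy_protocol(list(sgse_encoding(0.200, 0.735, g),
                      sgse_encoding(0.593, 0.580, g)),
                 tm_ms)
}

# dense matrix exponential (scaling-and-squaring via Matrix)
expm_dense <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

#' Simulate SGSE DEXSY signals by operator products
#'
#' Evaluates S(encoding, tm) = 1' O_D2 O_E O_D1 S0 with S0 the column of
#' site fractions, diffusion operators O_D = expm(-b D) and the mixing
#' operator O_E = expm(-tm (K + R1)). Exchange and spin-spin relaxation
#' during the (sub-millisecond) encoding periods are negligible when
#' tau << 1/k and tau << T2 and are off by default; setting the flags adds
#' the -2 tau K and -2 tau R2 terms to the encoding operators.
#'
#' @param system A [compartment_system()].
#' @param spec An exchange specification (see [exchange_two_site()]).
#' @param protocol A [dexsy_protocol()].
#' @param include_encoding_exchange Include exchange during encoding blocks.
#' @param include_R2 Include spin-spin relaxation during encoding blocks.
#' @return A `signal_table` data frame with columns `encoding`, `tau1_ms`,
#'   `tau2_ms`, `b1`, `b2`, `tm_ms`, `signal`. Signals are normalized to a
#'   total magnetization of 1 at b = 0, tm = 0.
#' @examples
#' sys <- system_three_site(0.32)
#' tab <- simulate_dexsy(sys, exchange_three_site(300, 30),
#'                       dexsy_protocol_default())
#' head(tab)
#' @export
simulate_dexsy <- function(system, spec, protocol,
                           include_encoding_exchange = FALSE,
                           include_R2 = FALSE) {
  stopifnot(inherits(system, "compartment_system"),
            inherits(protocol, "dexsy_protocol"))
  n <- system$n_sites
  K <- build_exchange_matrix(spec, system$f)
  if (nrow(K) != n) stop("exchange matrix dimension does not match system")
  D <- diag(system$ADC, n)
  R1 <- diag(system$R1, n)
  R2 <- diag(system$R2, n)
  S0 <- system$f

  rows <- vector("list", length(protocol$encodings))
  for (e in seq_along(protocol$encodings)) {
    enc <- protocol$encodings[[e]]
    M1 <- -enc$b1 * D
    M2 <- -enc$b2 * D
    if (include_encoding_exchange) {
      M1 <- M1 - 2 * enc$tau1_ms * 1e-3 * K
      M2 <- M2 - 2 * enc$tau2_ms * 1e-3 * K
    }
    if (include_R2) {
      M1 <- M1 - 2 * enc$tau1_ms * 1e-3 * R2
      M2 <- M2 - 2 * enc$tau2_ms * 1e-3 * R2
    }
    OD1 <- expm_dense(M1)
    OD2 <- expm_dense(M2)
    s_in <- OD1 %*% S0
    sig <- vapply(protocol$tm_ms, function(tm) {
      OE <- expm_dense(-(tm * 1e-3) * (K + R1))
      sum(OD2 %*% (OE %*% s_in))
    }, numeric(1))
    rows[[e]] <- data.frame(encoding = e, tau1_ms = enc$tau1_ms,
                            tau2_ms = enc$tau2_ms, b1 = enc$b1, b2 = enc$b2,
                            tm_ms = protocol$tm_ms, signal = sig)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("signal_table", "data.frame")
  out
}

#' Fraction-weighted apparent diffusion coefficient
#'
#' Predicts the ensemble ADC as the sum of per-site ADCs weighted by their
#' signal fractions.
#'
#' @param system A [compartment_system()].
#' @return ADC in um^2/ms.
#' @export
predict_adc <- function(system) {
  stopifnot(inherits(system, "compartment_system"))
  sum(system$f * system$ADC)
}

#' Monte-Carlo particle oracle for DEXSY signals
#'
#' Independent estimate of the operator-product signal by simulating
#' particles that hop between sites as a continuous-time Markov chain with
#' jump rates taken from the exchange matrix. Each particle starts in a site
#' drawn from the equilibrium fractions and carries the weight
#' exp(-b1 ADC(site at encoding 1)) * exp(-integral of R1 over the mixing
#' time) * exp(-b2 ADC(site at tm)); the signal is the mean weight. Used as
#' a cross-check of [simulate_dexsy()] under its default options (no
#' exchange or R2 during encoding).
#'
#' @inheritParams simulate_dexsy
#' @param n_particles Number of particles per protocol cell.
#' @param seed Integer seed; output is reproducible for a fixed seed.
#' @return A data frame like [simulate_dexsy()] with an extra column `se`,
#'   the per-cell standard error of the Monte-Carlo mean.
#' @export
ctmc_oracle <- function(system, spec, protocol, n_particles = 1e5, seed = 1) {
  stopifnot(inherits(system, "compartment_system"),
            inherits(protocol, "dexsy_protocol"))
  if (n_particles < 1) stop("`n_particles` must be >= 1")
  K <- build_exchange_matrix(spec, system$f)
  n_sites <- system$n_sites
  exit <- diag(K)
  # jump probability matrix: P[j, i] = P(next site is j | leaving i)
  P <- matrix(0, n_sites, n_sites)
  for (i in seq_len(n_sites)) if (exit[i] > 0) {
    P[, i] <- pmax(-K[, i], 0) / exit[i]
    P[i, i] <- 0
  }
  cumP <- apply(P, 2, cumsum)

  set.seed(seed)
  rows <- vector("list", length(protocol$encodings))
  for (e in seq_along(protocol$encodings)) {
    enc <- protocol$encodings[[e]]
    sig <- numeric(length(protocol$tm_ms))
    se <- numeric(length(protocol$tm_ms))
    for (j in seq_along(protocol$tm_ms)) {
      tm_s <- protocol$tm_ms[j] * 1e-3
      st <- sample.int(n_sites, n_particles, replace = TRUE, prob = system$f)
      w <- exp(-enc$b1 * system$ADC[st])
      accR <- numeric(n_particles)
      t_now <- numeric(n_particles)
      active <- seq_len(n_particles)
      while (length(active) > 0) {
        s <- st[active]
        r <- exit[s]
        hold <- ifelse(r > 0, stats::rexp(length(active)) / r, Inf)
        t_next <- t_now[active] + hold
        accR[active] <- accR[active] +
          (pmin(t_next, tm_s) - t_now[active]) * system$R1[s]
        jump <- t_next < tm_s
        idx <- active[jump]
        if (length(idx) > 0) {
          u <- stats::runif(length(idx))
          s_from <- st[idx]
          new_s <- integer(length(idx))
          for (i in seq_len(n_sites)) {
            sel <- s_from == i
            if (any(sel))
              new_s[sel] <- findInterval(u[sel], cumP[, i],
                                         left.open = TRUE) + 1L
          }
          st[idx] <- new_s
          t_now[idx] <- t_next[jump]
        }
        active <- idx
      }
      w <- w * exp(-accR) * exp(-enc$b2 * system$ADC[st])
      sig[j] <- mean(w)
      se[j] <- stats::sd(w) / sqrt(n_particles)
    }
    rows[[e]] <- data.frame(encoding = e, tau1_ms = enc$tau1_ms,
                            tau2_ms = enc$tau2_ms, b1 = enc$b1, b2 = enc$b2,
                            tm_ms = protocol$tm_ms, signal = sig, se = se)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("signal_table", "data.frame")
  out
}
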