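## Perturbative models of Hardy-Weinberg violations of the dosage
## distribution: selfing under polysomic or disomic inheritance, and
## dosage-dependent selection, all at linear order in the small parameter.
## Deviations are vectors Delta I_k over dosage classes 0..p with
## sum_k Delta I_k = 0 (and sum_k k Delta I_k = 0 for the inheritance
## scenarios, which conserve allele frequency).

.kernel_cache <- new.env(parent = emptyenv())

#' Gamete dosage kernel
#'
#' Probability that a gamete receives `a` derived alleles when p/2 of a
#' parent's p chromosomes, `parent_dosage` of them derived, are sampled
#' without replacement (polysomic meiosis, no double reduction): the
#' hypergeometric pmf.
#'
#' @param a derived alleles in the gamete, `0..p/2`; vectorized.
#' @param parent_dosage parental dosage k', `0..p`.
#' @param ploidy ploidy p.
#' @return Probabilities, summing to 1 over `a = 0..p/2`.
#' @export
gamete_kernel <- function(a, parent_dosage, ploidy) {
  check_ploidy(ploidy)
  if (any(a < 0 | a > ploidy / 2))
    stop("gamete dosage must lie in [0, ploidy/2]", call. = FALSE)
  dhyper(a, parent_dosage, ploidy - parent_dosage, ploidy / 2)
}

## Offspring kernel under random mating: K[k+1, k'+1, k''+1].
mating_kernel <- function(p) {
  key <- paste0("mate", p)
  if (!is.null(.kernel_cache[[key]])) return(.kernel_cache[[key]])
  gam <- sapply(0:p, function(kp) dhyper(0:(p / 2), kp, p - kp, p / 2))
  arr <- array(0, c(p + 1, p + 1, p + 1))
  for (kp in 0:p) for (kpp in 0:p) {
    off <- convolve_coeffs(gam[, kp + 1], gam[, kpp + 1])
    arr[seq_along(off), kp + 1, kpp + 1] <- off
  }
  .kernel_cache[[key]] <- arr
  arr
}

## Selfing kernel, polysomic: offspring dosage pmf given one parent k'.
selfing_kernel_polysomic <- function(p) {
  key <- paste0("selfp", p)
  if (!is.null(.kernel_cache[[key]])) return(.kernel_cache[[key]])
  gam <- sapply(0:p, function(kp) dhyper(0:(p / 2), kp, p - kp, p / 2))
  Tk <- sapply(0:p, function(kp) {
    off <- convolve_coeffs(gam[, kp + 1], gam[, kp + 1])
    c(off, numeric(p + 1 - length(off)))
  })
  .kernel_cache[[key]] <- Tk
  Tk
}

## Selfing kernel, disomic: the parent's k' derived alleles are arranged
## uniformly over the p chromosomes held in p/2 fixed homolog pairs; each
## heterozygous pair segregates independently like a selfing diploid locus
## (offspring pair dosage Binomial(2, 1/2)), homozygous pairs breed true.
selfing_kernel_disomic <- function(p) {
  key <- paste0("selfd", p)
  if (!is.null(.kernel_cache[[key]])) return(.kernel_cache[[key]])
  np <- p / 2
  Tk <- matrix(0, p + 1, p + 1)
  for (kp in 0:p) {
    for (h in 0:min(np, kp)) {
      m <- (kp - h) / 2            # derived-homozygous pairs
      if (m != floor(m) || m < 0 || m > np - h) next
      p_h <- choose(np, h) * choose(np - h, m) * 2^h / choose(p, kp)
      if (p_h == 0) next
      t <- 0:(2 * h)               # derived alleles from the het pairs
      k <- kp - h + t
      Tk[k + 1, kp + 1] <- Tk[k + 1, kp + 1] + p_h * dbinom(t, 2 * h, 0.5)
    }
  }
  .kernel_cache[[key]] <- Tk
  Tk
}

new_hw_perturbation <- function(delta, ploidy, scenario, frequency,
                                params = list()) {
  out <- tibble::tibble(dosage = 0:ploidy, delta = as.numeric(delta))
  structure(out, class = c("hw_perturbation", class(out)),
            ploidy = ploidy, scenario = scenario, frequency = frequency,
            params = params)
}

#' @export
print.hw_perturbation <- function(x, ...) {
  f <- attr(x, "frequency")
  cat(sprintf("<hw_perturbation> scenario '%s', ploidy %d, %s\n",
              attr(x, "scenario"), attr(x, "ploidy"),
              if (is.na(f)) "integrated over theta/f" else paste0("f = ", f)))
  NextMethod()
}

#' Residual of the random-mating equilibrium condition
#'
#' Evaluates how far a dosage distribution is from being a fixed point of
#' one generation of random mating with polysomic inheritance. Every
#' Hardy-Weinberg binomial distribution (any f) gives a zero residual, as
#' does a fixed allele.
#'
#' @param dd numeric vector of dosage-class fractions `i_0..i_p`, summing
#'   to 1.
#' @param ploidy ploidy p.
#' @return `dd - next_generation(dd)`, length p+1.
#' @export
random_mating_residual <- function(dd, ploidy) {
  check_ploidy(ploidy)
  if (length(dd) != ploidy + 1 || abs(sum(dd) - 1) > 1e-8)
    stop("dd must be a normalized vector of length ploidy + 1", call. = FALSE)
  K <- mating_kernel(ploidy)
  nxt <- vapply(0:ploidy, function(k) sum(outer(dd, dd) * K[k + 1, , ]), 0)
  dd - nxt
}

check_freq_open <- function(f) {
  if (f <= 0 || f >= 1)
    stop("frequency must lie strictly inside (0, 1)", call. = FALSE)
  invisible(f)
}

check_small <- function(x, what) {
  if (any(abs(x) > 0.2))
    warning(what, " above 0.2: linear perturbation theory is questionable")
  invisible(x)
}

#' Dosage-distribution perturbation from occasional selfing
#'
#' Linear-order deviation of the DD from its Hardy-Weinberg value when a
#' small fraction `selfing_rate` of offspring are produced by selfing under
#' polysomic inheritance:
#' `Delta I_k = p_s * (sum_k' I^eq_k' Self(k | k') - I^eq_k)`.
#' Mass- and frequency-conserving; produces an excess of homozygotes.
#'
#' @param f variant frequency in (0, 1).
#' @param ploidy ploidy p.
#' @param selfing_rate selfing probability p_s (small; warned above 0.2).
#' @return An `hw_perturbation` tibble (`dosage`, `delta`).
#' @export
selfing_perturbation <- function(f, ploidy, selfing_rate = 0.01) {
  check_ploidy(ploidy); check_freq_open(f)
  check_small(selfing_rate, "selfing_rate")
  I0 <- hw_dosage_distribution(ploidy, f)
  Tk <- selfing_kernel_polysomic(ploidy)
  new_hw_perturbation(selfing_rate * (as.vector(Tk %*% I0) - I0), ploidy,
                      "selfing", f, list(selfing_rate = selfing_rate))
}

#' Selfing perturbation under purely disomic inheritance
#'
#' As [selfing_perturbation()] but with fixed homolog pairs segregating
#' independently (disomic inheritance): each heterozygous pair selfs like a
#' diploid locus. Relative to the polysomic case this shifts the
#' homozygote excess toward even dosage classes.
#'
#' @inheritParams selfing_perturbation
#' @return An `hw_perturbation`.
#' @export
disomic_selfing_perturbation <- function(f, ploidy, selfing_rate = 0.01) {
  check_ploidy(ploidy); check_freq_open(f)
  check_small(selfing_rate, "selfing_rate")
  I0 <- hw_dosage_distribution(ploidy, f)
  Tk <- selfing_kernel_disomic(ploidy)
  new_hw_perturbation(selfing_rate * (as.vector(Tk %*% I0) - I0), ploidy,
                      "disomic_selfing", f, list(selfing_rate = selfing_rate))
}

#' Selfing perturbation under mixed disomic/polysomic inheritance
#'
#' Convex combination of the purely polysomic and purely disomic selfing
#' perturbations with weights `1 - disomy_prob` and `disomy_prob`.
#'
#' @inheritParams selfing_perturbation
#' @param disomy_prob probability of disomic inheritance, `[0, 1]`.
#' @return An `hw_perturbation`.
#' @export
mixed_inheritance_perturbation <- function(f, ploidy, selfing_rate = 0.01,
                                           disomy_prob = 0.5) {
  stopifnot(disomy_prob >= 0, disomy_prob <= 1)
  a <- selfing_perturbation(f, ploidy, selfing_rate)
  b <- disomic_selfing_perturbation(f, ploidy, selfing_rate)
  new_hw_perturbation((1 - disomy_prob) * a$delta + disomy_prob * b$delta,
                      ploidy, "mixed_inheritance", f,
                      list(selfing_rate = selfing_rate,
                           disomy_prob = disomy_prob))
}

#' Fitness schemes for dosage-dependent selection
#'
#' Builds the vector of selection coefficients `s_0..s_p` for the two
#' canonical presets: constant advantage `s` for every heterozygous dosage
#' (`heterozygote_advantage`), or disadvantage `-s` for the derived
#' homozygote only (`recessive_deleterious`).
#'
#' @param ploidy ploidy p.
#' @param preset one of `"heterozygote_advantage"`, `"recessive_deleterious"`.
#' @param s magnitude of the selection coefficient (small).
#' @return Numeric vector of length p+1.
#' @export
fitness_scheme <- function(ploidy,
                           preset = c("heterozygote_advantage",
                                      "recessive_deleterious"),
                           s = 0.01) {
  check_ploidy(ploidy)
  preset <- match.arg(preset)
  out <- numeric(ploidy + 1)
  if (preset == "heterozygote_advantage") out[2:ploidy] <- s
  else out[ploidy + 1] <- -s
  out
}

#' Dosage-distribution perturbation from weak dosage-dependent selection
#'
#' Linearizes the selection + random-mating map around the Hardy-Weinberg
#' equilibrium at frequency f for fitnesses `1 + s_k` per dosage class k.
#' Because the HW equilibria form a one-parameter family in f, the
#' stationary linear system is singular along the frequency direction; when
#' the scheme shifts the allele frequency (e.g. recessive deleterious
#' selection), the deviation is defined as the quasi-steady shape relative
#' to the Hardy-Weinberg distribution at the (slowly drifting) current
#' frequency, obtained from the drift-corrected system
#' `[(I - M) + w k^T M / p] dI = b - w (k^T b) / p` with `b = M (I0 * s)`
#' and `w = d HW / d f`. Mass is conserved (`sum(delta) = 0`); allele
#' frequency is held fixed by construction (`sum(k * delta) = 0`).
#'
#' @param f variant frequency in (0, 1).
#' @param ploidy ploidy p.
#' @param s numeric vector `s_0..s_p` of selection coefficients (see
#'   [fitness_scheme()]), all small (warned above 0.2).
#' @return An `hw_perturbation`.
#' @export
selection_perturbation <- function(f, ploidy, s) {
  check_ploidy(ploidy); check_freq_open(f)
  if (length(s) != ploidy + 1)
    stop("s must have length ploidy + 1", call. = FALSE)
  check_small(s, "selection coefficients")
  p <- ploidy
  I0 <- hw_dosage_distribution(p, f)
  K <- mating_kernel(p)
  M <- matrix(0, p + 1, p + 1)
  for (kpp in 0:p)
    M[, kpp + 1] <- vapply(0:p, function(k) 2 * sum(I0 * K[k + 1, , kpp + 1]), 0) -
      2 * I0
  b <- as.vector(M %*% (I0 * s))
  kv <- 0:p
  w <- dbinom(kv, p, f) * (kv / f - (p - kv) / (1 - f))  # d HW / d f
  A <- (diag(p + 1) - M) + (w %*% t(kv) %*% M) / p
  rhs <- b - w * sum(kv * b) / p
  delta <- tryCatch(solve(A, rhs), error = function(e) {
    warning("drift-corrected system singular; using pseudoinverse ",
            "projected onto the mass-conserving subspace")
    x <- as.vector(MASS::ginv(A) %*% rhs)
    x - mean(x)
  })
  new_hw_perturbation(as.vector(delta), p, "selection", f, list(s = s))
}

#' Frequency-integrated deviation shape
#'
#' Integrates a pointwise DD deviation against the neutral site-frequency
#' density theta/f over a frequency grid, giving the expected deviation
#' shape for random neutral mutations. The absolute amplitude is arbitrary
#' (it scales with theta and the perturbation parameter); only the shape
#' and signs are meaningful.
#'
#' @param perturb_fn function of f returning an `hw_perturbation` or a
#'   numeric vector of length ploidy + 1.
#' @param ploidy ploidy p.
#' @param theta weight scale for the neutral density (default 1).
#' @param grid frequencies to integrate over (midpoint rule on a uniform
#'   grid by default).
#' @return An `hw_perturbation` with `frequency = NA` and scenario tagged
#'   `"integrated"`.
#' @export
integrate_over_neutral_frequencies <- function(perturb_fn, ploidy, theta = 1,
                                               grid = seq(0.01, 0.99,
                                                          length.out = 197)) {
  check_ploidy(ploidy)
  if (length(grid) == 0) stop("empty frequency grid", call. = FALSE)
  step <- if (length(grid) > 1) diff(grid)[1] else 1
  acc <- numeric(ploidy + 1)
  scen <- "integrated"
  for (f in grid) {
    d <- perturb_fn(f)
    if (inherits(d, "hw_perturbation")) {
      scen <- paste0(attr(d, "scenario"), "_integrated")
      d <- d$delta
    }
    acc <- acc + (theta / f) * d * step
  }
  new_hw_perturbation(acc, ploidy, scen, NA_real_, list(theta = theta))
}

#' Single-individual SFS under a dosage-distribution deviation
#'
#' For a sample of one individual the SFS *is* the heterozygous part of the
#' dosage distribution: classes d = 1..p-1, since homozygous sites are not
#' seen as polymorphisms. The neutral expectation is `theta / d`; a DD
#' deviation adds its heterozygous components. The homozygous components of
#' the deviation are dropped (the deviation of the visible spectrum need
#' not sum to zero).
#'
#' @param deviation an `hw_perturbation` (typically frequency-integrated)
#'   or numeric vector of length ploidy + 1.
#' @param ploidy ploidy p.
#' @param theta scale of the neutral part (default 1).
#' @return Tibble with columns `dosage` (1..p-1), `xi_neutral` and
#'   `delta_xi`.
#' @export
single_individual_sfs <- function(deviation, ploidy, theta = 1) {
  check_ploidy(ploidy)
  if (inherits(deviation, "hw_perturbation")) deviation <- deviation$delta
  stopifnot(length(deviation) == ploidy + 1)
  d <- seq_len(ploidy - 1L)
  tibble::tibble(dosage = d, xi_neutral = theta / d,
                 delta_xi = deviation[d + 1L])
}

#' Direction of a perturbation in the (Tajima D, Fay-Wu H) plane
#'
#' Linear response of the two test numerators to a deviation of the
#' single-individual SFS (p chromosomes): D responds through
#' `theta_pi - theta_W` and H through `2 (theta_pi - theta_L)` with the
#' classical SFS weights, normalized to a unit vector. The standard
#' Fay-Wu/Zeng sign convention is used: an excess of high-frequency derived
#' classes drives H negative.
#'
#' @param perturbed_sfs result of [single_individual_sfs()] (its `delta_xi`
#'   is used) or a numeric vector of SFS deviations over classes 1..p-1.
#' @param ploidy ploidy p.
#' @return Named unit vector `c(D, H)` with attribute `"numerators"`
#'   holding the unnormalized responses; the zero vector for a zero
#'   perturbation.
#' @export
test_direction <- function(perturbed_sfs, ploidy) {
  check_ploidy(ploidy)
  dxi <- if (is.data.frame(perturbed_sfs)) perturbed_sfs$delta_xi
         else as.numeric(perturbed_sfs)
  stopifnot(length(dxi) == ploidy - 1L)
  m <- ploidy
  d <- seq_len(m - 1L)
  w_pi <- 2 * d * (m - d) / (m * (m - 1))
  w_w <- 1 / sum(1 / d)
  w_l <- d / (m - 1)
  num <- c(D = sum((w_pi - w_w) * dxi), H = 2 * sum((w_pi - w_l) * dxi))
  len <- sqrt(sum(num^2))
  dir <- if (len > 0) num / len else num * 0
  structure(dir, numerators = num)
}
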