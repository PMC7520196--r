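#' Configuration for the synthetic monitoring simulator
#'
#' Builds and validates the parameter set that drives [simulate_population()]
#' and [corrupt_to_replicates()]. Defaults describe a small two-sex alpine
#' hare population monitored over five years with two sampling sessions per
#' year (spring mating season, fall post-reproduction), seven biallelic
#' microsatellite loci plus a male-specific dominant sex marker, and the
#' error structure typical of fecal-DNA genotyping: per-replicate allelic
#' dropout, sporadic false alleles, failed (missing) replicates, sex-marker
#' dropout in males, and per-capture misidentification that creates unique
#' "ghost" genotypes.
#'
#' @param n_loci number of biallelic microsatellite loci.
#' @param alleles_per_locus integer vector (length `n_loci`) of allele counts.
#' @param allele_freqs list of per-locus allele frequency vectors; each must
#'   sum to 1. Default: frequencies proportional to `1/i`, a moderately
#'   skewed spectrum with one common allele per locus.
#' @param locus_names character vector of locus labels.
#' @param n_females,n_males initial population sizes per sex.
#' @param phi_f,phi_m apparent survival per between-session interval, by sex.
#' @param gamma_dprime probability an on-site animal temporarily emigrates
#'   before the next primary occasion (gamma'').
#' @param gamma_prime probability a temporary emigrant stays off-site
#'   (gamma'); `1 - gamma_prime` is the return rate.
#' @param p_capture,c_recapture 2 x 2 matrices (rows `F`,`M`; columns
#'   `spring`,`fall`) of per-secondary-occasion capture and recapture
#'   probabilities.
#' @param alpha probability a capture is assigned to the correct individual
#'   genotype; scalar, or a 2 x 2 sex-by-season matrix.
#' @param dropout_rate per-replicate probability that a heterozygous
#'   replicate loses one allele (apparent homozygote).
#' @param false_allele_rate per-replicate probability of gaining a novel
#'   artifact allele.
#' @param missing_replicate_rate per replicate-locus probability of complete
#'   amplification failure.
#' @param sry_dropout per-replicate probability that the sex marker fails to
#'   amplify in a male sample.
#' @param n_pso number of primary sampling occasions (sessions).
#' @param sso_per_pso secondary occasions (sampling days) per session;
#'   scalar or vector of length `n_pso`.
#' @param seasons season label per session (`"spring"`/`"fall"`); default
#'   alternates starting in spring.
#' @param recruits_per_interval 2-column matrix (`F`,`M`) with one row per
#'   between-session interval: new individuals entering the population.
#'   Default 0 (closed population).
#' @param systematic_prob probability a collected sample comes from the
#'   systematic grid rather than opportunistic search.
#' @param n_replicates PCR replicates per sample (multi-tube approach).
#' @param seed integer root seed; every random draw in the simulator derives
#'   from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_pso = 2, seed = 42)
#' cfg$alleles_per_locus
sim_config <- function(n_loci = 7,
                       alleles_per_locus = c(3, 5, 7, 2, 6, 3, 5),
                       allele_freqs = NULL,
                       locus_names = NULL,
                       n_females = 13,
                       n_males = 17,
                       phi_f = 0.90,
                       phi_m = 0.76,
                       gamma_dprime = 0.05,
                       gamma_prime = 0.77,
                       p_capture = matrix(c(0.26, 0.26, 0.25, 0.17), 2, 2,
                         dimnames = list(c("F", "M"), c("spring", "fall"))),
                       c_recapture = matrix(c(0.34, 0.44, 0.22, 0.21), 2, 2,
                         dimnames = list(c("F", "M"), c("spring", "fall"))),
                       alpha = 0.85,
                       dropout_rate = 0.10,
                       false_allele_rate = 0.02,
                       missing_replicate_rate = 0.15,
                       sry_dropout = 0.20,
                       n_pso = 10,
                       sso_per_pso = 8,
                       seasons = NULL,
                       recruits_per_interval = NULL,
                       systematic_prob = 0.19,
                       n_replicates = 3,
                       seed = 1L) {
  stopifnot(n_loci >= 1, length(alleles_per_locus) == n_loci,
            all(alleles_per_locus >= 1))
  if (is.null(locus_names)) {
    locus_names <- if (n_loci == 7) {
      c("Lsa1", "Lsa3", "Sat5", "Sat8", "Sol30", "Sol33", "Sol8")
    } else {
      sprintf("L%02d", seq_len(n_loci))
    }
  }
  stopifnot(length(locus_names) == n_loci, !anyDuplicated(locus_names))
  if (is.null(allele_freqs)) {
    allele_freqs <- lapply(alleles_per_locus, function(a) {
      w <- 1 / seq_len(a)
      w / sum(w)
    })
  }
  stopifnot(length(allele_freqs) == n_loci)
  for (l in seq_len(n_loci)) {
    f <- allele_freqs[[l]]
    if (length(f) != alleles_per_locus[l] || any(f < 0) ||
        abs(sum(f) - 1) > 1e-12) {
      stop("allele_freqs[[", l, "]] must be a probability vector of length ",
           alleles_per_locus[l], " summing to 1")
    }
  }
  if (length(alpha) == 1) {
    alpha <- matrix(alpha, 2, 2,
                    dimnames = list(c("F", "M"), c("spring", "fall")))
  }
  .check_rate_matrix(p_capture, "p_capture")
  .check_rate_matrix(c_recapture, "c_recapture")
  .check_rate_matrix(alpha, "alpha")
  probs <- c(phi_f = phi_f, phi_m = phi_m, gamma_dprime = gamma_dprime,
             gamma_prime = gamma_prime, dropout_rate = dropout_rate,
             false_allele_rate = false_allele_rate,
             missing_replicate_rate = missing_replicate_rate,
             sry_dropout = sry_dropout, systematic_prob = systematic_prob)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("probabilities outside [0,1]: ",
                     paste(names(probs)[bad], collapse = ", "))
  stopifnot(n_pso >= 1, n_females >= 0, n_males >= 0, n_replicates >= 1)
  if (length(sso_per_pso) == 1) sso_per_pso <- rep(sso_per_pso, n_pso)
  stopifnot(length(sso_per_pso) == n_pso, all(sso_per_pso >= 1))
  if (is.null(seasons)) {
    seasons <- rep(c("spring", "fall"), length.out = n_pso)
  }
  stopifnot(length(seasons) == n_pso, all(seasons %in% c("spring", "fall")))
  if (is.null(recruits_per_interval)) {
    recruits_per_interval <- matrix(0L, max(n_pso - 1, 0), 2,
                                    dimnames = list(NULL, c("F", "M")))
  }
  recruits_per_interval <- as.matrix(recruits_per_interval)
  stopifnot(nrow(recruits_per_interval) == max(n_pso - 1, 0),
            ncol(recruits_per_interval) == 2,
            all(recruits_per_interval >= 0))
  colnames(recruits_per_interval) <- c("F", "M")
  seed <- as.integer(seed)
  stopifnot(!is.na(seed))

  cfg <- list(
    n_loci = as.integer(n_loci),
    alleles_per_locus = as.integer(alleles_per_locus),
    allele_freqs = allele_freqs,
    locus_names = locus_names,
    n_females = as.integer(n_females),
    n_males = as.integer(n_males),
    phi_f = phi_f, phi_m = phi_m,
    gamma_dprime = gamma_dprime, gamma_prime = gamma_prime,
    p_capture = p_capture, c_recapture = c_recapture, alpha = alpha,
    dropout_rate = dropout_rate, false_allele_rate = false_allele_rate,
    missing_replicate_rate = missing_replicate_rate,
    sry_dropout = sry_dropout,
    n_pso = as.integer(n_pso),
    sso_per_pso = as.integer(sso_per_pso),
    seasons = seasons,
    recruits_per_interval = recruits_per_interval,
    systematic_prob = systematic_prob,
    n_replicates = as.integer(n_replicates),
    seed = seed
  )
  class(cfg) <- "sim_config"
  cfg
}

.check_rate_matrix <- function(m, name) {
  if (!is.matrix(m) || !all(dim(m) == c(2, 2)) || any(m < 0) || any(m > 1)) {
    stop(name, " must be a 2x2 matrix (F/M x spring/fall) of probabilities")
  }
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic monitoring configuration\n")
  cat(sprintf("  population : %d F + %d M, %d sessions (%s)\n",
              x$n_females, x$n_males, x$n_pso,
              paste(substr(x$seasons, 1, 2), collapse = "/")))
  cat(sprintf("  panel      : %d loci (%s alleles)\n", x$n_loci,
              paste(x$alleles_per_locus, collapse = ",")))
  cat(sprintf("  errors     : dropout %.2f, false allele %.3f, missing %.2f, SRY dropout %.2f\n",
              x$dropout_rate, x$false_allele_rate,
              x$missing_replicate_rate, x$sry_dropout))
  cat(sprintf("  misID alpha: %s\n",
              paste(format(x$alpha, digits = 2), collapse = " ")))
  cat(sprintf("  seed       : %d\n", x$seed))
  invisible(x)
}
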