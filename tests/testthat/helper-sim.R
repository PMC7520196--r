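# shared fixture builders for the test suite

# study-scale configuration used by the CMR recovery checks: generating
# values near the monitored population's estimates
recovery_config <- function(seed) {
  sim_config(
    n_females = 18, n_males = 18,
    phi_f = 0.9, phi_m = 0.76,
    gamma_dprime = 0.05, gamma_prime = 0.77,
    p_capture = matrix(0.25, 2, 2,
                       dimnames = list(c("F", "M"), c("spring", "fall"))),
    c_recapture = matrix(0.30, 2, 2,
                         dimnames = list(c("F", "M"), c("spring", "fall"))),
    alpha = 0.85,
    n_pso = 10, sso_per_pso = 8,
    recruits_per_interval = matrix(rep(c(2L, 4L), 9), 9, 2, byrow = TRUE),
    seed = seed)
}

# error-free, highly polymorphic configuration: every capture genotyped
# perfectly, loci diverse enough that distinct individuals never fall
# within the mismatch threshold
errorfree_config <- function(seed, n_females = 25, n_males = 25,
                             n_pso = 4, p = 0.35) {
  sim_config(
    n_loci = 7, alleles_per_locus = rep(8L, 7),
    allele_freqs = replicate(7, rep(1 / 8, 8), simplify = FALSE),
    n_females = n_females, n_males = n_males,
    phi_f = 1, phi_m = 1, gamma_dprime = 0, gamma_prime = 1,
    p_capture = matrix(p, 2, 2,
                       dimnames = list(c("F", "M"), c("spring", "fall"))),
    c_recapture = matrix(p, 2, 2,
                         dimnames = list(c("F", "M"), c("spring", "fall"))),
    alpha = 1, dropout_rate = 0, false_allele_rate = 0,
    missing_replicate_rate = 0, sry_dropout = 0,
    n_pso = n_pso, sso_per_pso = 5, seed = seed)
}

# minimal single-session capture_histories object built by hand
manual_histories <- function(det, group, seasons = NULL, sso_counts = NULL) {
  T <- dim(det)[2]
  if (is.null(seasons)) seasons <- rep(c("spring", "fall"), length.out = T)
  if (is.null(sso_counts)) sso_counts <- rep(dim(det)[3], T)
  ids <- sprintf("i%03d", seq_len(dim(det)[1]))
  dimnames(det) <- list(ids, sprintf("pso%02d", seq_len(T)), NULL)
  structure(list(det = det, group = stats::setNames(group, ids),
                 seasons = seasons, sso_counts = as.integer(sso_counts),
                 sessions = sprintf("pso%02d", seq_len(T))),
            class = "capture_histories")
}

# replicate-table row builder for consensus tests
rep_rows <- function(sample_id, locus, pairs, session = "pso01", day = 1,
                     method = "systematic", sry = FALSE) {
  do.call(rbind, lapply(seq_along(pairs), function(r) {
    data.frame(sample_id = sample_id, session = session, day = day,
               method = method, locus = locus, replicate = r,
               allele1 = pairs[[r]][1], allele2 = pairs[[r]][2],
               sry_amplified = sry, stringsAsFactors = FALSE)
  }))
}
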