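#' Simulate a monitored population and its capture process
#'
#' Runs the generating model forward: a two-sex population with per-locus
#' allele frequencies evolves between primary sampling occasions (PSOs) as a
#' Markov chain per individual (apparent survival `phi` by sex, Markovian
#' temporary emigration `gamma''`/`gamma'`), and is sampled within each PSO
#' on secondary occasions (SSOs) with first-capture probability `p` and
#' recapture probability `c`, both sex- and season-specific. Every capture
#' is assigned to the correct individual genotype with probability `alpha`;
#' a misassigned capture spawns a ghost record carrying a unique fabricated
#' genotype, the mechanism by which genotyping error inflates apparent
#' individual counts.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `sim_truth`: list with
#'   \describe{
#'     \item{individuals}{data frame of true individuals (id, sex, entry PSO).}
#'     \item{genotypes}{long data frame of true genotypes
#'       (individual_id, locus, allele1, allele2).}
#'     \item{alive, onsite}{logical matrices individual x PSO.}
#'     \item{capture_events}{data frame (event_id, individual_id, pso, sso,
#'       sex, method, is_ghost, ghost_id).}
#'     \item{ghost_records}{data frame mapping each ghost to its source
#'       capture event, plus the fabricated ghost genotypes in
#'       `ghost_genotypes`.}
#'     \item{calendar}{data frame (session, pso, season, n_days).}
#'   }
#' @export
#' @examples
#' truth <- simulate_population(sim_config(n_pso = 2, seed = 7))
#' nrow(truth$capture_events)
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  n0 <- cfg$n_females + cfg$n_males
  exp_caps <- n0 * sum(cfg$sso_per_pso) * max(cfg$p_capture)
  if (n0 == 0 && sum(cfg$recruits_per_interval) == 0) {
    stop("configuration has zero individuals: nothing to simulate")
  }

  T <- cfg$n_pso
  # individuals: initial cohort, then recruits per interval
  sexes <- c(rep("F", cfg$n_females), rep("M", cfg$n_males))
  entry <- rep(1L, n0)
  if (T > 1) {
    for (iv in seq_len(T - 1)) {
      rf <- cfg$recruits_per_interval[iv, "F"]
      rm_ <- cfg$recruits_per_interval[iv, "M"]
      sexes <- c(sexes, rep("F", rf), rep("M", rm_))
      entry <- c(entry, rep(iv + 1L, rf + rm_))
    }
  }
  n <- length(sexes)
  ids <- sprintf("T%03d", seq_len(n))

  # true genotypes
  geno <- array(NA_integer_, c(n, cfg$n_loci, 2))
  for (l in seq_len(cfg$n_loci)) {
    codes <- 98L + 2L * seq_len(cfg$alleles_per_locus[l])
    a <- matrix(sample(codes, 2 * n, replace = TRUE,
                       prob = cfg$allele_freqs[[l]]), n, 2)
    geno[, l, ] <- t(apply(a, 1, sort))
  }

  # state evolution
  alive <- onsite <- matrix(FALSE, n, T, dimnames = list(ids, NULL))
  for (i in seq_len(n)) alive[i, entry[i]] <- onsite[i, entry[i]] <- TRUE
  phi <- ifelse(sexes == "F", cfg$phi_f, cfg$phi_m)
  if (T > 1) {
    for (t in seq_len(T - 1)) {
      present <- alive[, t]
      surv <- present & (stats::runif(n) < phi)
      alive[, t + 1] <- alive[, t + 1] | surv
      was_on <- onsite[, t]
      goes_off <- stats::runif(n) < cfg$gamma_dprime
      stays_off <- stats::runif(n) < cfg$gamma_prime
      nxt <- ifelse(was_on, !goes_off, !stays_off)
      onsite[, t + 1] <- onsite[, t + 1] | (surv & nxt)
    }
  }

  # capture process
  ev <- list()
  ghosts <- list()
  ghost_n <- 0L
  ev_n <- 0L
  for (t in seq_len(T)) {
    season <- cfg$seasons[t]
    avail <- which(alive[, t] & onsite[, t])
    caught_before <- rep(FALSE, n)
    for (j in seq_len(cfg$sso_per_pso[t])) {
      for (i in avail) {
        pr <- if (caught_before[i]) cfg$c_recapture[sexes[i], season]
              else cfg$p_capture[sexes[i], season]
        if (stats::runif(1) < pr) {
          caught_before[i] <- TRUE
          ev_n <- ev_n + 1L
          is_ghost <- stats::runif(1) >= cfg$alpha[sexes[i], season]
          gid <- NA_character_
          if (is_ghost) {
            ghost_n <- ghost_n + 1L
            gid <- sprintf("G%04d", ghost_n)
            ghosts[[ghost_n]] <- data.frame(
              ghost_id = gid, event_id = ev_n,
              individual_id = ids[i], pso = t, sso = j,
              sex = sexes[i], stringsAsFactors = FALSE)
          }
          ev[[ev_n]] <- data.frame(
            event_id = ev_n, individual_id = ids[i], pso = t, sso = j,
            sex = sexes[i],
            method = if (stats::runif(1) < cfg$systematic_prob)
              "systematic" else "opportunistic",
            is_ghost = is_ghost, ghost_id = gid, stringsAsFactors = FALSE)
        }
      }
    }
  }
  capture_events <- if (ev_n > 0) do.call(rbind, ev) else
    data.frame(event_id = integer(), individual_id = character(),
               pso = integer(), sso = integer(), sex = character(),
               method = character(), is_ghost = logical(),
               ghost_id = character())
  ghost_records <- if (ghost_n > 0) do.call(rbind, ghosts) else
    data.frame(ghost_id = character(), event_id = integer(),
               individual_id = character(), pso = integer(),
               sso = integer(), sex = character())

  # fabricated ghost genotypes: unique reserved allele codes, heterozygous
  # at every locus, so a ghost can never match a real or another ghost
  # genotype within the mismatch threshold
  ghost_geno <- NULL
  if (ghost_n > 0) {
    ghost_geno <- do.call(rbind, lapply(seq_len(ghost_n), function(k) {
      data.frame(ghost_id = sprintf("G%04d", k),
                 locus = cfg$locus_names,
                 allele1 = 9000L + 2L * k,
                 allele2 = 9001L + 2L * k,
                 stringsAsFactors = FALSE)
    }))
  }

  genotypes <- do.call(rbind, lapply(seq_len(cfg$n_loci), function(l) {
    data.frame(individual_id = ids, locus = cfg$locus_names[l],
               allele1 = geno[, l, 1], allele2 = geno[, l, 2],
               stringsAsFactors = FALSE)
  }))
  genotypes <- genotypes[order(genotypes$individual_id, genotypes$locus), ]
  rownames(genotypes) <- NULL

  out <- list(
    individuals = data.frame(individual_id = ids, sex = sexes,
                             entry_pso = entry, stringsAsFactors = FALSE),
    genotypes = genotypes,
    alive = alive, onsite = onsite,
    capture_events = capture_events,
    ghost_records = ghost_records,
    ghost_genotypes = ghost_geno,
    calendar = data.frame(session = sprintf("pso%02d", seq_len(T)),
                          pso = seq_len(T), season = cfg$seasons,
                          n_days = cfg$sso_per_pso,
                          stringsAsFactors = FALSE),
    config = cfg
  )
  class(out) <- "sim_truth"
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "Simulated truth: %d individuals, %d sessions, %d capture events (%d ghosts)\n",
    nrow(x$individuals), x$config$n_pso, nrow(x$capture_events),
    nrow(x$ghost_records)))
  invisible(x)
}

#' Corrupt true capture events into replicated genotype tables
#'
#' Each capture event yields one fecal sample genotyped in `n_replicates`
#' independent PCR replicates per locus (multi-tube approach). Replicates of
#' heterozygous genotypes lose one allele (chosen uniformly) with probability
#' `dropout_rate`, becoming apparent homozygotes; any replicate gains a novel
#' artifact allele with probability `false_allele_rate`; whole replicate-locus
#' amplifications fail with probability `missing_replicate_rate`. The sex
#' marker amplifies per replicate with probability `1 - sry_dropout` for male
#' samples and never for females. Misidentified events are genotyped from
#' their fabricated ghost genotype instead of the source individual's.
#'
#' @param truth a [simulate_population()] result.
#' @param config the same [sim_config()] used to generate `truth`.
#' @return data frame with one row per sample x locus x replicate:
#'   `sample_id, session, day, method, locus, replicate, allele1, allele2,
#'   sry_amplified`, plus an attribute `"sample_truth"` mapping samples to
#'   their source (individual or ghost).
#' @export
corrupt_to_replicates <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (!identical(truth$config$seed, config$seed)) {
    stop("truth was generated under a different configuration seed")
  }
  cfg <- config
  set.seed(cfg$seed + 1L)  # replicate-corruption sub-stream of the root seed

  evs <- truth$capture_events
  n_ev <- nrow(evs)
  if (n_ev == 0) {
    return(structure(data.frame(sample_id = character(), session = character(),
                                day = integer(), method = character(),
                                locus = character(), replicate = integer(),
                                allele1 = integer(), allele2 = integer(),
                                sry_amplified = logical()),
                     sample_truth = data.frame()))
  }

  # source genotype lookup: individual or ghost
  truegeno <- truth$genotypes
  key <- paste(truegeno$individual_id, truegeno$locus)
  g1 <- stats::setNames(truegeno$allele1, key)
  g2 <- stats::setNames(truegeno$allele2, key)
  if (!is.null(truth$ghost_genotypes)) {
    gkey <- paste(truth$ghost_genotypes$ghost_id, truth$ghost_genotypes$locus)
    g1 <- c(g1, stats::setNames(truth$ghost_genotypes$allele1, gkey))
    g2 <- c(g2, stats::setNames(truth$ghost_genotypes$allele2, gkey))
  }

  R <- cfg$n_replicates
  L <- cfg$n_loci
  rows <- vector("list", n_ev)
  for (e in seq_len(n_ev)) {
    src <- if (evs$is_ghost[e]) evs$ghost_id[e] else evs$individual_id[e]
    sample_id <- sprintf("S%05d", evs$event_id[e])
    male <- evs$sex[e] == "M"
    a1 <- g1[paste(src, cfg$locus_names)]
    a2 <- g2[paste(src, cfg$locus_names)]
    out1 <- out2 <- matrix(NA_integer_, L, R)
    sry <- matrix(FALSE, L, R)
    for (r in seq_len(R)) {
      miss <- stats::runif(L) < cfg$missing_replicate_rate
      b1 <- a1; b2 <- a2
      het <- b1 != b2
      drop <- het & (stats::runif(L) < cfg$dropout_rate)
      if (any(drop)) {
        keep_first <- stats::runif(sum(drop)) < 0.5
        kept <- ifelse(keep_first, b1[drop], b2[drop])
        b1[drop] <- kept; b2[drop] <- kept
      }
      fa <- stats::runif(L) < cfg$false_allele_rate
      if (any(fa)) {
        novel <- 5000L + sample.int(999L, sum(fa), replace = TRUE)
        which_allele <- stats::runif(sum(fa)) < 0.5
        b1[fa] <- ifelse(which_allele, novel, b1[fa])
        b2[fa] <- ifelse(which_allele, b2[fa], novel)
      }
      swap <- !is.na(b1) & b1 > b2
      if (any(swap)) { tmp <- b1[swap]; b1[swap] <- b2[swap]; b2[swap] <- tmp }
      b1[miss] <- NA_integer_; b2[miss] <- NA_integer_
      out1[, r] <- b1; out2[, r] <- b2
      sry[, r] <- male && (stats::runif(1) >= cfg$sry_dropout)
    }
    rows[[e]] <- data.frame(
      sample_id = sample_id,
      session = sprintf("pso%02d", evs$pso[e]),
      day = evs$sso[e],
      method = evs$method[e],
      locus = rep(cfg$locus_names, R),
      replicate = rep(seq_len(R), each = L),
      allele1 = as.vector(out1), allele2 = as.vector(out2),
      sry_amplified = as.vector(sry),
      stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  attr(reps, "sample_truth") <- data.frame(
    sample_id = sprintf("S%05d", evs$event_id),
    source_id = ifelse(evs$is_ghost, evs$ghost_id, evs$individual_id),
    individual_id = evs$individual_id,
    is_ghost = evs$is_ghost,
    pso = evs$pso, sso = evs$sso, sex = evs$sex, method = evs$method,
    stringsAsFactors = FALSE)
  reps
}

#' Simulate a complete replicated-genotype dataset
#'
#' Convenience wrapper running [simulate_population()] and
#' [corrupt_to_replicates()] under one configuration.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `truth` and `replicates`.
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_population(config)
  list(truth = truth, replicates = corrupt_to_replicates(truth, config))
}

#' Write / read a simulated dataset as plain text
#'
#' `write_simulation()` stores the replicate table as CSV and the ground
#' truth (parameters, individual list, ghost list) as a JSON sidecar;
#' `read_replicates()` reads any replicate-genotype CSV with the standard
#' columns back in.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return `write_simulation()` returns the paths invisibly;
#'   `read_replicates()` returns the replicate data frame.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rep_path <- file.path(dir, "replicates.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(sim$replicates, rep_path, row.names = FALSE)
  tr <- sim$truth
  payload <- list(
    config = tr$config[setdiff(names(tr$config),
                               c("allele_freqs", "p_capture", "c_recapture",
                                 "alpha", "recruits_per_interval"))],
    allele_freqs = tr$config$allele_freqs,
    p_capture = tr$config$p_capture,
    c_recapture = tr$config$c_recapture,
    alpha = tr$config$alpha,
    individuals = tr$individuals,
    genotypes = tr$genotypes,
    capture_events = tr$capture_events,
    ghost_records = tr$ghost_records,
    calendar = tr$calendar
  )
  jsonlite::write_json(payload, truth_path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(replicates = rep_path, truth = truth_path))
}

#' @rdname write_simulation
#' @param path CSV file with columns `sample_id, session, day, method,
#'   locus, replicate, allele1, allele2, sry_amplified`.
#' @export
read_replicates <- function(path) {
  reps <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "session", "day", "method", "locus", "replicate",
              "allele1", "allele2", "sry_amplified")
  missing_cols <- setdiff(needed, names(reps))
  if (length(missing_cols)) {
    stop("replicate table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  reps$sry_amplified <- as.logical(reps$sry_amplified)
  reps
}

#' Capture histories straight from simulated truth
#'
#' Bypasses the genotyping and identification stages: builds the
#' robust-design detection array directly from the simulator's capture
#' events. With `observed = TRUE` (default) the histories are the observed
#' view -- correctly identified captures accrue to their individual, each
#' misidentified capture appears as its own single-detection ghost row.
#' With `observed = FALSE` the true histories (all captures assigned to
#' their real individual) are returned.
#'
#' @param truth a [simulate_population()] result.
#' @param observed return the ghost-inflated observed view?
#' @return a `capture_histories` object (see [build_histories()]).
#' @export
simulated_histories <- function(truth, observed = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  ev <- truth$capture_events
  if (observed) {
    owner <- ifelse(ev$is_ghost, ev$ghost_id, ev$individual_id)
  } else {
    owner <- ev$individual_id
  }
  ids <- unique(owner[order(ev$pso, ev$sso, owner)])
  T <- truth$config$n_pso
  K <- max(truth$config$sso_per_pso)
  det <- array(0L, c(length(ids), T, K),
               dimnames = list(ids, truth$calendar$session, NULL))
  for (t in seq_len(T)) {
    det[, t, seq_len(K) > truth$config$sso_per_pso[t]] <- NA_integer_
  }
  det[cbind(match(owner, ids), ev$pso, ev$sso)] <- 1L
  sex <- stats::setNames(truth$individuals$sex, truth$individuals$individual_id)
  grp <- ifelse(is.na(sex[ids]), NA_character_, sex[ids])
  if (nrow(truth$ghost_records) > 0) {
    gsex <- stats::setNames(truth$ghost_records$sex, truth$ghost_records$ghost_id)
    grp[is.na(grp)] <- gsex[ids[is.na(grp)]]
  }
  out <- list(det = det, group = stats::setNames(grp, ids),
              seasons = truth$config$seasons,
              sso_counts = truth$config$sso_per_pso,
              sessions = truth$calendar$session)
  class(out) <- "capture_histories"
  out
}
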