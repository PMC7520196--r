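#' Consensus call for one locus from replicated genotypes
#'
#' Applies the multi-tube consensus rules: a homozygote `A/A` is accepted
#' only if all `R` replicates amplified and equal `A/A`; a heterozygote
#' `A/B` is accepted if at least two replicates equal `A/B` and no allele
#' outside `{A, B}` occurs in any non-missing replicate. Anything else is
#' no call.
#'
#' @param replicates numeric matrix with `R` rows and 2 columns (allele
#'   pairs, `NA`/`NA` for a failed replicate), or a list of length-2
#'   vectors.
#' @return integer vector `c(allele1, allele2)`, or `NULL` for no call.
#' @export
#' @examples
#' call_consensus_locus(rbind(c(1, 2), c(1, 2), c(1, 1)))  # 1 2
#' call_consensus_locus(rbind(c(1, 1), c(1, 1), c(NA, NA)))  # no call
call_consensus_locus <- function(replicates) {
  if (is.list(replicates)) replicates <- do.call(rbind, replicates)
  stopifnot(is.matrix(replicates), ncol(replicates) == 2, nrow(replicates) >= 1)
  miss <- is.na(replicates[, 1])
  if (any(xor(miss, is.na(replicates[, 2])))) {
    stop("a replicate must have both alleles present or both missing")
  }
  obs <- replicates[!miss, , drop = FALSE]
  if (nrow(obs) == 0) return(NULL)
  obs <- t(apply(obs, 1, sort))

  # homozygote rule: all R replicates present and identical homozygotes
  if (!any(miss) && all(obs[, 1] == obs[, 2]) &&
      length(unique(obs[, 1])) == 1) {
    return(c(obs[1, 1], obs[1, 2]))
  }
  # heterozygote rule: >=2 concordant heterozygote replicates, allele union
  # confined to that pair
  pair_key <- paste(obs[, 1], obs[, 2])
  het <- obs[, 1] != obs[, 2]
  if (any(het)) {
    tab <- table(pair_key[het])
    best <- names(tab)[which.max(tab)]
    if (max(tab) >= 2) {
      pair <- as.numeric(strsplit(best, " ")[[1]])
      if (all(unique(as.vector(obs)) %in% pair)) {
        return(pair)
      }
    }
  }
  NULL
}

#' Sex call from sex-marker amplification flags
#'
#' A sample is called male if the dominant Y-linked marker amplified in at
#' least one replicate, female if it never amplified.
#'
#' @param flags logical vector of per-replicate amplification indicators.
#' @return `"M"` or `"F"`.
#' @export
call_sex <- function(flags) {
  stopifnot(length(flags) >= 1)
  if (any(as.logical(flags), na.rm = TRUE)) "M" else "F"
}

#' Consensus genotype for one sample
#'
#' @param sample_reps replicate rows for a single sample (columns `locus`,
#'   `replicate`, `allele1`, `allele2`, `sry_amplified`).
#' @param loci character vector: the full biallelic locus panel. Loci in
#'   `sample_reps` not listed here raise an error.
#' @param min_loci minimum number of successfully scored loci for the
#'   multilocus consensus genotype to be accepted (default 6 of 7).
#' @return list with `calls` (data frame locus/allele1/allele2, `NA` for no
#'   call), `n_scored`, `accepted`, `sex`.
#' @export
call_consensus_sample <- function(sample_reps, loci, min_loci = 6) {
  unknown <- setdiff(unique(sample_reps$locus), loci)
  if (length(unknown)) {
    stop("unknown loci in replicate table: ", paste(unknown, collapse = ", "))
  }
  calls <- data.frame(locus = loci, allele1 = NA_real_, allele2 = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(loci)) {
    lr <- sample_reps[sample_reps$locus == loci[i], , drop = FALSE]
    if (nrow(lr) == 0) next
    lr <- lr[order(lr$replicate), , drop = FALSE]
    cl <- call_consensus_locus(as.matrix(lr[, c("allele1", "allele2")]))
    if (!is.null(cl)) {
      calls$allele1[i] <- cl[1]
      calls$allele2[i] <- cl[2]
    }
  }
  n_scored <- sum(!is.na(calls$allele1))
  list(calls = calls, n_scored = n_scored,
       accepted = n_scored >= min_loci,
       sex = call_sex(sample_reps$sry_amplified))
}

#' Consensus genotypes for a replicate table
#'
#' Runs [call_consensus_sample()] over every sample of a replicate-genotype
#' table and assembles the per-sample consensus set used by the individual
#' identification step.
#'
#' @param reps replicate table with columns `sample_id, session, day,
#'   method, locus, replicate, allele1, allele2, sry_amplified`.
#' @param min_loci acceptance threshold on scored loci (default 6).
#' @param loci locus panel; defaults to the loci present in `reps`, sorted.
#' @param patterns optional data frame of qualitative pattern-locus classes
#'   (`sample_id, locus, class`); carried through for identity resolution,
#'   never entering consensus scoring.
#' @return object of class `consensus_set`: list with `samples` (per-sample
#'   data frame: session, day, method, sex, n_scored, accepted), `calls`
#'   (long data frame of per-locus consensus calls), `loci`, `min_loci`,
#'   `patterns`.
#' @export
call_consensus <- function(reps, min_loci = 6, loci = NULL, patterns = NULL) {
  stopifnot(nrow(reps) > 0)
  if (is.null(loci)) loci <- sort(unique(reps$locus))
  sids <- sort(unique(reps$sample_id))
  idx <- split(seq_len(nrow(reps)), reps$sample_id)

  samples <- vector("list", length(sids))
  calls <- vector("list", length(sids))
  for (k in seq_along(sids)) {
    sr <- reps[idx[[sids[k]]], , drop = FALSE]
    res <- call_consensus_sample(sr, loci, min_loci)
    samples[[k]] <- data.frame(
      sample_id = sids[k], session = sr$session[1], day = sr$day[1],
      method = sr$method[1], sex = res$sex, n_scored = res$n_scored,
      accepted = res$accepted, stringsAsFactors = FALSE)
    calls[[k]] <- cbind(sample_id = sids[k], res$calls)
  }
  out <- list(samples = do.call(rbind, samples),
              calls = do.call(rbind, calls),
              loci = loci, min_loci = min_loci, patterns = patterns)
  rownames(out$samples) <- rownames(out$calls) <- NULL
  class(out) <- "consensus_set"
  out
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("Consensus genotypes: %d samples, %d loci, %d accepted (%.1f%%)\n",
              nrow(x$samples), length(x$loci), sum(x$samples$accepted),
              100 * mean(x$samples$accepted)))
  cat(sprintf("  sex calls: %d F / %d M; acceptance rule: >= %d loci scored\n",
              sum(x$samples$sex == "F"), sum(x$samples$sex == "M"),
              x$min_loci))
  invisible(x)
}

#' Proportion of missing replicate genotypes
#'
#' The missing-data error rate: the proportion of replicate-locus slots in
#' the raw genotype table that failed to amplify, computed per sample and
#' summarized by group. Group means carry the standard error of the
#' per-sample proportions within the group.
#'
#' @param reps replicate table (see [call_consensus()]).
#' @param by grouping: `"session"`, `"locus"`, or `"sample"`.
#' @return data frame with columns `group`, `rate` (mean per-sample
#'   proportion), `se`, `n_samples`.
#' @export
missing_rate <- function(reps, by = c("session", "locus", "sample")) {
  by <- match.arg(by)
  stopifnot(nrow(reps) > 0)
  miss <- is.na(reps$allele1)
  per_sample <- function(rows) {
    tapply(miss[rows], reps$sample_id[rows], mean)
  }
  groups <- switch(by,
    session = split(seq_len(nrow(reps)), reps$session),
    locus = split(seq_len(nrow(reps)), reps$locus),
    sample = split(seq_len(nrow(reps)), reps$sample_id))
  out <- lapply(names(groups), function(g) {
    rates <- per_sample(groups[[g]])
    data.frame(group = g, rate = mean(rates),
               se = if (length(rates) > 1)
                 stats::sd(rates) / sqrt(length(rates)) else NA_real_,
               n_samples = length(rates), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' False-homozygote rate in consensus heterozygote genotypes
#'
#' Among sample/locus combinations whose consensus genotype was scored as a
#' heterozygote, the proportion of non-missing replicates that are
#' (apparent) homozygotes -- the observable signature of allelic dropout.
#' The pooled rate divides homozygous replicates by all non-missing
#' replicates in qualifying combinations; the standard error is that of the
#' per-sample proportions within the group.
#'
#' @param reps raw replicate table.
#' @param consensus the [call_consensus()] result computed from `reps`.
#' @param by grouping: `"session"` or `"locus"`.
#' @return data frame `group, rate, se, n_replicates, n_samples`; `rate` is
#'   `NA` where no consensus heterozygote exists in the group.
#' @export
false_homozygote_rate <- function(reps, consensus,
                                  by = c("session", "locus")) {
  by <- match.arg(by)
  stopifnot(inherits(consensus, "consensus_set"))
  het <- consensus$calls[!is.na(consensus$calls$allele1) &
                           consensus$calls$allele1 != consensus$calls$allele2,
                         c("sample_id", "locus")]
  key <- paste(reps$sample_id, reps$locus)
  qual <- key %in% paste(het$sample_id, het$locus)
  use <- qual & !is.na(reps$allele1)
  is_hom <- reps$allele1 == reps$allele2

  grp_all <- switch(by, session = reps$session, locus = reps$locus)
  out <- lapply(sort(unique(grp_all)), function(g) {
    sel <- use & grp_all == g
    n <- sum(sel)
    if (n == 0) {
      return(data.frame(group = g, rate = NA_real_, se = NA_real_,
                        n_replicates = 0L, n_samples = 0L,
                        stringsAsFactors = FALSE))
    }
    rates <- tapply(is_hom[sel], reps$sample_id[sel], mean)
    data.frame(group = g, rate = sum(is_hom[sel]) / n,
               se = if (length(rates) > 1)
                 stats::sd(rates) / sqrt(length(rates)) else NA_real_,
               n_replicates = n, n_samples = length(rates),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
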