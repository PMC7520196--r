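#' Allele mismatch distance between two multilocus genotypes
#'
#' Per shared non-missing locus the mismatch count is the number of alleles
#' that cannot be matched in a maximal pairing of the two allele pairs
#' (0, 1 or 2); qualitative pattern loci contribute 2 mismatches when their
#' classes differ and 0 when equal; loci missing in either genotype are
#' skipped.
#'
#' @param g1,g2 data frames with columns `locus, allele1, allele2` on the
#'   same locus panel (`NA` alleles = missing locus).
#' @param p1,p2 optional named character vectors of pattern-locus classes.
#' @return list with `mismatches` and `compared_loci`; `mismatches` is `NA`
#'   when no locus is comparable.
#' @export
#' @examples
#' a <- data.frame(locus = "L1", allele1 = 1, allele2 = 2)
#' b <- data.frame(locus = "L1", allele1 = 1, allele2 = 3)
#' genotype_distance(a, b)$mismatches  # 1
genotype_distance <- function(g1, g2, p1 = NULL, p2 = NULL) {
  m <- merge(g1, g2, by = "locus", suffixes = c(".1", ".2"))
  ok <- !is.na(m$allele1.1) & !is.na(m$allele1.2)
  m <- m[ok, , drop = FALSE]
  mm <- 0L
  if (nrow(m) > 0) {
    direct <- (m$allele1.1 == m$allele1.2) + (m$allele2.1 == m$allele2.2)
    crossed <- (m$allele1.1 == m$allele2.2) + (m$allele2.1 == m$allele1.2)
    mm <- sum(2L - pmax(direct, crossed))
  }
  n_cmp <- nrow(m)
  if (!is.null(p1) && !is.null(p2)) {
    shared <- intersect(names(p1)[!is.na(p1)], names(p2)[!is.na(p2)])
    mm <- mm + 2L * sum(p1[shared] != p2[shared])
    n_cmp <- n_cmp + length(shared)
  }
  if (n_cmp == 0) return(list(mismatches = NA_integer_, compared_loci = 0L))
  list(mismatches = as.integer(mm), compared_loci = as.integer(n_cmp))
}

#' Cluster accepted consensus genotypes into individuals
#'
#' Single-linkage grouping of accepted multilocus consensus genotypes under
#' an allele-mismatch threshold, the mechanized form of genotype matching:
#' two samples belong to the same individual when they differ by at most
#' `max_mismatch` alleles (pattern loci included, weighted 2 per differing
#' class). Samples are processed in sorted `sample_id` order so the result
#' is invariant to input row order; pairs sharing fewer than
#' `min_shared_loci` comparable biallelic loci never merge. Each
#' individual's genotype is the modal allele pair per locus across member
#' samples; individual ids are assigned in order of first detection.
#'
#' @param consensus a [call_consensus()] result.
#' @param max_mismatch merge threshold on mismatched alleles (default 2).
#' @param min_shared_loci minimum comparable biallelic loci for a merge
#'   (default 5), guarding against sparse-genotype collapse.
#' @param calendar optional data frame (`session, pso, season, n_days`);
#'   default derives session order by sorted label.
#' @return object of class `individual_set`: `individuals` (id, sex,
#'   n_samples, n_false_female, first_session), `genotypes` (long modal
#'   genotypes), `members` (sample-to-individual map with session/day/
#'   method/sample sex), `borderline` (merged pairs at distance 1-2,
#'   flagged for manual review).
#' @export
cluster_individuals <- function(consensus, max_mismatch = 2,
                                min_shared_loci = 5, calendar = NULL) {
  stopifnot(inherits(consensus, "consensus_set"))
  acc <- consensus$samples[consensus$samples$accepted, , drop = FALSE]
  if (nrow(acc) == 0) stop("no accepted consensus genotypes to cluster")
  sids <- sort(acc$sample_id)
  n <- length(sids)
  calls <- consensus$calls[consensus$calls$sample_id %in% sids, , drop = FALSE]

  loci <- consensus$loci
  A1 <- A2 <- matrix(NA_real_, n, length(loci),
                     dimnames = list(sids, loci))
  ix <- cbind(match(calls$sample_id, sids), match(calls$locus, loci))
  A1[ix] <- calls$allele1
  A2[ix] <- calls$allele2

  pat <- NULL
  if (!is.null(consensus$patterns)) {
    pl <- sort(unique(consensus$patterns$locus))
    pat <- matrix(NA_character_, n, length(pl), dimnames = list(sids, pl))
    keep <- consensus$patterns$sample_id %in% sids
    pp <- consensus$patterns[keep, , drop = FALSE]
    pat[cbind(match(pp$sample_id, sids), match(pp$locus, pl))] <- pp$class
  }

  # pairwise distance, single linkage via union-find in deterministic order
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  borderline <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ok <- !is.na(A1[i, ]) & !is.na(A1[j, ])
      if (sum(ok) < min_shared_loci) next
      direct <- (A1[i, ok] == A1[j, ok]) + (A2[i, ok] == A2[j, ok])
      crossed <- (A1[i, ok] == A2[j, ok]) + (A2[i, ok] == A1[j, ok])
      d <- sum(2L - pmax(direct, crossed))
      if (!is.null(pat)) {
        sh <- !is.na(pat[i, ]) & !is.na(pat[j, ])
        d <- d + 2L * sum(pat[i, sh] != pat[j, sh])
      }
      if (d <= max_mismatch) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        if (d > 0) {
          borderline[[length(borderline) + 1]] <-
            data.frame(sample1 = sids[i], sample2 = sids[j], mismatches = d,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  acc <- acc[match(sids, acc$sample_id), , drop = FALSE]

  # order clusters by first detection (session order, then day, then id)
  if (is.null(calendar)) {
    sess <- sort(unique(acc$session))
    calendar <- data.frame(session = sess, pso = seq_along(sess),
                           stringsAsFactors = FALSE)
  }
  acc$pso <- calendar$pso[match(acc$session, calendar$session)]
  if (anyNA(acc$pso)) stop("sample with unknown session label")
  ord_key <- order(acc$pso, acc$day, acc$sample_id)
  first_seen <- ord_key[!duplicated(root[ord_key])]
  cluster_ids <- root[first_seen]
  id_map <- stats::setNames(sprintf("NP%03d", seq_along(cluster_ids)),
                            cluster_ids)
  ind_id <- unname(id_map[as.character(root)])

  members <- data.frame(sample_id = sids, individual_id = ind_id,
                        session = acc$session, day = acc$day,
                        method = acc$method, sex = acc$sex,
                        pso = acc$pso, stringsAsFactors = FALSE)

  # modal genotype per cluster and locus (ties -> smallest allele pair)
  genotypes <- do.call(rbind, lapply(unname(id_map), function(id) {
    rows <- which(ind_id == id)
    do.call(rbind, lapply(seq_along(loci), function(l) {
      a1 <- A1[rows, l]; a2 <- A2[rows, l]
      ok <- !is.na(a1)
      if (!any(ok)) {
        return(data.frame(individual_id = id, locus = loci[l],
                          allele1 = NA_real_, allele2 = NA_real_,
                          stringsAsFactors = FALSE))
      }
      keys <- paste(a1[ok], a2[ok])
      tab <- sort(table(keys), decreasing = TRUE)
      best <- names(tab)[tab == max(tab)]
      pair <- as.numeric(strsplit(sort(best)[1], " ")[[1]])
      data.frame(individual_id = id, locus = loci[l],
                 allele1 = pair[1], allele2 = pair[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(genotypes) <- NULL

  agg <- split(members, members$individual_id)
  individuals <- do.call(rbind, lapply(unname(id_map), function(id) {
    m <- agg[[id]]
    data.frame(individual_id = id,
               sex = if (any(m$sex == "M")) "M" else "F",
               n_samples = nrow(m),
               n_false_female = 0L,
               first_session = m$session[order(m$pso, m$day)][1],
               stringsAsFactors = FALSE)
  }))
  rownames(individuals) <- NULL

  out <- list(individuals = individuals, genotypes = genotypes,
              members = members,
              borderline = if (length(borderline))
                do.call(rbind, borderline) else NULL,
              calendar = calendar, resolved = FALSE)
  class(out) <- "individual_set"
  resolve_sex(out)
}

#' Reclassify false females inside male genotype groups
#'
#' A female-called sample clustered with one or more male-called samples is
#' reclassified as male and counted as a false female: the dominant sex
#' marker can drop out, so an all-negative sample from a male is called
#' female at the sample level. Clusters containing only female-called
#' samples stay female.
#'
#' @param inds an `individual_set` from [cluster_individuals()] (which
#'   already applies this rule; calling it again is idempotent).
#' @return the `individual_set` with per-individual sex finalized and
#'   `n_false_female` counts filled in.
#' @export
resolve_sex <- function(inds) {
  stopifnot(inherits(inds, "individual_set"))
  for (k in seq_len(nrow(inds$individuals))) {
    id <- inds$individuals$individual_id[k]
    sx <- inds$members$sex[inds$members$individual_id == id]
    male <- any(sx == "M")
    inds$individuals$sex[k] <- if (male) "M" else "F"
    inds$individuals$n_false_female[k] <- if (male) sum(sx == "F") else 0L
  }
  inds$resolved <- TRUE
  inds
}

#' @export
print.individual_set <- function(x, ...) {
  cat(sprintf("Identified individuals: %d (%d F / %d M) from %d samples\n",
              nrow(x$individuals), sum(x$individuals$sex == "F"),
              sum(x$individuals$sex == "M"), nrow(x$members)))
  ff <- sum(x$individuals$n_false_female)
  if (ff > 0) cat(sprintf("  false females reclassified: %d\n", ff))
  if (!is.null(x$borderline)) {
    cat(sprintf("  borderline merges (1-2 mismatches) flagged: %d\n",
                nrow(x$borderline)))
  }
  invisible(x)
}

#' Build robust-design capture histories
#'
#' Converts identified individuals' sample records into a binary detection
#' array individual x primary occasion x secondary occasion, with sex as
#' group label and the session calendar's season labels attached.
#'
#' @param inds an `individual_set`.
#' @param calendar data frame `session, pso, season, n_days` ordered
#'   chronologically.
#' @param systematic_only if `TRUE`, only samples collected on the
#'   systematic grid count as detections.
#' @return object of class `capture_histories`: `det` (3-d 0/1 array, `NA`
#'   beyond a session's day count), `group` (sex per individual), `seasons`,
#'   `sso_counts`.
#' @export
build_histories <- function(inds, calendar, systematic_only = FALSE) {
  stopifnot(inherits(inds, "individual_set"))
  stopifnot(all(c("session", "pso", "season", "n_days") %in% names(calendar)))
  calendar <- calendar[order(calendar$pso), , drop = FALSE]
  mem <- inds$members
  if (systematic_only) mem <- mem[mem$method == "systematic", , drop = FALSE]
  if (!all(mem$session %in% calendar$session)) {
    stop("sample with unknown session label")
  }
  T <- nrow(calendar)
  K <- max(calendar$n_days)
  ids <- inds$individuals$individual_id
  det <- array(0L, c(length(ids), T, K),
               dimnames = list(ids, calendar$session, NULL))
  for (t in seq_len(T)) det[, t, seq_len(K) > calendar$n_days[t]] <- NA_integer_
  if (nrow(mem) > 0) {
    pso <- calendar$pso[match(mem$session, calendar$session)]
    if (any(mem$day < 1 | mem$day > calendar$n_days[pso])) {
      stop("sample day outside its session's secondary occasions")
    }
    det[cbind(match(mem$individual_id, ids), pso, mem$day)] <- 1L
  }
  keep <- apply(det, 1, function(m) sum(m, na.rm = TRUE)) > 0
  out <- list(det = det[keep, , , drop = FALSE],
              group = stats::setNames(inds$individuals$sex, ids)[keep],
              seasons = calendar$season,
              sso_counts = calendar$n_days,
              sessions = calendar$session)
  class(out) <- "capture_histories"
  out
}

#' @export
print.capture_histories <- function(x, ...) {
  cat(sprintf(
    "Capture histories: %d individuals (%d F / %d M), %d primary x <=%d secondary occasions\n",
    dim(x$det)[1], sum(x$group == "F"), sum(x$group == "M"),
    dim(x$det)[2], dim(x$det)[3]))
  cat(sprintf("  detections: %d; seasons: %s\n",
              sum(x$det, na.rm = TRUE),
              paste(substr(x$seasons, 1, 2), collapse = "/")))
  invisible(x)
}

#' Export capture histories in MARK-style .inp encoding
#'
#' One line per individual: the concatenated 0/1 detection string over all
#' secondary occasions of all primary occasions, followed by one frequency
#' column per group (`1 0` female, `0 1` male) and a terminating semicolon.
#'
#' @param histories a [build_histories()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_inp <- function(histories, path) {
  stopifnot(inherits(histories, "capture_histories"))
  n <- dim(histories$det)[1]
  lines <- vapply(seq_len(n), function(i) {
    bits <- unlist(lapply(seq_along(histories$sso_counts), function(t) {
      histories$det[i, t, seq_len(histories$sso_counts[t])]
    }))
    grp <- if (histories$group[i] == "F") "1 0" else "0 1"
    sprintf("/* %s */ %s %s;", dimnames(histories$det)[[1]][i],
            paste(bits, collapse = ""), grp)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
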