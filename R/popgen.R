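#' Per-locus population-genetic summary
#'
#' Computes the marker-panel statistics for one microsatellite locus from
#' individual genotypes (one genotype per identified individual): number of
#' alleles A, individuals typed N, observed heterozygosity `H_O`, unbiased
#' expected heterozygosity `H_E = (2n/(2n-1)) (1 - sum p_i^2)`, polymorphic
#' information content
#' `PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`, probability of identity
#' for unrelated individuals
#' `P_ID = sum p_i^4 + sum_{i<j} (2 p_i p_j)^2`, its sibling counterpart
#' `P_IDsib = 0.25 + 0.5 sum p_i^2 + 0.5 (sum p_i^2)^2 - 0.25 sum p_i^4`,
#' and the Chakraborty null-allele estimate
#' `F_null = (H_E - H_O) / (H_E + H_O)`.
#'
#' @param genotypes data frame with columns `allele1, allele2`, one row per
#'   typed individual (`NA` rows dropped), or `NULL` when `freqs` is given.
#' @param freqs optional allele frequency vector (frequency-only mode:
#'   `H_O` and `F_null` are then `NA` and `H_E` is the plug-in
#'   `1 - sum p_i^2`).
#' @return one-row data frame `A, N, H_O, H_E, PIC, P_ID, P_IDsib, F_null`.
#' @export
#' @examples
#' summarize_locus(freqs = c(0.5, 0.5))  # P_ID 0.375, P_IDsib 0.59375
summarize_locus <- function(genotypes = NULL, freqs = NULL) {
  if (is.null(freqs)) {
    stopifnot(!is.null(genotypes))
    g <- genotypes[!is.na(genotypes$allele1), , drop = FALSE]
    n <- nrow(g)
    stopifnot(n >= 2)
    alleles <- c(g$allele1, g$allele2)
    p <- as.vector(table(alleles)) / (2 * n)
    H_O <- mean(g$allele1 != g$allele2)
    s2 <- sum(p^2)
    H_E <- (2 * n / (2 * n - 1)) * (1 - s2)
  } else {
    stopifnot(all(freqs >= 0), abs(sum(freqs) - 1) < 1e-9)
    p <- freqs
    n <- NA_integer_
    H_O <- NA_real_
    s2 <- sum(p^2)
    H_E <- 1 - s2
  }
  s4 <- sum(p^4)
  pp <- outer(p, p)
  off <- upper.tri(pp)
  PIC <- 1 - s2 - 2 * sum((p^2) %o% (p^2) * off)
  P_ID <- s4 + sum((2 * pp[off])^2)
  P_IDsib <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
  F_null <- if (!is.na(H_O) && (H_E + H_O) > 0)
    (H_E - H_O) / (H_E + H_O) else NA_real_
  data.frame(A = length(p), N = n, H_O = H_O, H_E = H_E, PIC = PIC,
             P_ID = P_ID, P_IDsib = P_IDsib, F_null = F_null)
}

#' Multilocus probability of identity
#'
#' Assuming locus independence, the probability that two individuals share
#' a full multilocus genotype is the product of the per-locus identity
#' probabilities (applies to both the unrelated and the sibling variant).
#'
#' @param pid_values numeric vector of per-locus `P_ID` (or `P_IDsib`)
#'   values in `(0, 1]`.
#' @return the across-loci product.
#' @export
#' @examples
#' multilocus_pid(c(0.504, 0.669, 0.565, 0.872, 0.629, 0.525, 0.662))
multilocus_pid <- function(pid_values) {
  stopifnot(length(pid_values) >= 1,
            all(pid_values > 0), all(pid_values <= 1))
  prod(pid_values)
}

#' Monte-Carlo exact test for Hardy-Weinberg equilibrium
#'
#' Permutation version of the exact test: alleles are shuffled among
#' genotypes and the conditional probability of each permuted genotype
#' table (given the allele counts) is compared with the observed table's;
#' the p-value is the fraction of permuted tables at most as probable as
#' the observed one.
#'
#' @param genotypes data frame `allele1, allele2`, one row per individual.
#' @param n_mc number of Monte-Carlo permutations (default 10^4).
#' @param seed integer seed for the permutation stream.
#' @return the Monte-Carlo p-value; exactly 1 for a monomorphic locus.
#' @export
hwe_test <- function(genotypes, n_mc = 10000, seed = 1L) {
  g <- genotypes[!is.na(genotypes$allele1), , drop = FALSE]
  n <- nrow(g)
  stopifnot(n >= 5)
  alleles <- c(g$allele1, g$allele2)
  if (length(unique(alleles)) == 1) return(1)

  log_table_prob <- function(a1, a2) {
    het <- sum(a1 != a2)
    key <- paste(pmin(a1, a2), pmax(a1, a2))
    sum_lf_geno <- sum(lgamma(table(key) + 1))
    het * log(2) - sum_lf_geno
  }
  # terms constant in the allele counts (n!, allele factorials, (2n)!)
  # cancel in the comparison, so only the genotype-dependent part is kept
  obs <- log_table_prob(g$allele1, g$allele2)
  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(n_mc)) {
    perm <- sample(alleles)
    a1 <- perm[seq_len(n)]
    a2 <- perm[n + seq_len(n)]
    if (log_table_prob(a1, a2) <= obs + 1e-9) hits <- hits + 1L
  }
  hits / n_mc
}

#' Panel-wide population-genetic summary table
#'
#' Applies [summarize_locus()] to every locus of an individual genotype
#' table and appends the across-loci row: mean A, H_O and H_E, the number
#' of individuals typed at all loci jointly reported as the maximum N, and
#' the across-loci products of `P_ID` and `P_IDsib`.
#'
#' @param genotypes long data frame `individual_id, locus, allele1,
#'   allele2` (one genotype per individual).
#' @param hwe if `TRUE`, adds a Monte-Carlo Hardy-Weinberg p-value column.
#' @param n_mc,seed passed to [hwe_test()].
#' @return data frame with one row per locus plus an `"Across"` row.
#' @export
popgen_summary <- function(genotypes, hwe = FALSE, n_mc = 10000, seed = 1L) {
  loci <- sort(unique(genotypes$locus))
  rows <- lapply(loci, function(l) {
    g <- genotypes[genotypes$locus == l, , drop = FALSE]
    out <- summarize_locus(g)
    if (hwe) {
      out$HWE_p <- if (sum(!is.na(g$allele1)) >= 5)
        hwe_test(g, n_mc = n_mc, seed = seed) else NA_real_
    }
    cbind(locus = l, out)
  })
  tab <- do.call(rbind, rows)
  across <- data.frame(locus = "Across", A = mean(tab$A), N = max(tab$N),
                       H_O = mean(tab$H_O), H_E = mean(tab$H_E),
                       PIC = NA_real_,
                       P_ID = multilocus_pid(tab$P_ID),
                       P_IDsib = multilocus_pid(tab$P_IDsib),
                       F_null = NA_real_)
  if (hwe) across$HWE_p <- NA_real_
  out <- rbind(tab, across)
  rownames(out) <- NULL
  out
}
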