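#' Individuals-by-alleles indicator matrix
#'
#' Recodes multilocus genotypes as allele counts: one column per observed
#' allele per locus, holding the number of copies (0, 1 or 2) the
#' individual carries. Loci missing in an individual are imputed with the
#' column mean (computed over typed individuals); columns are centered.
#' Individuals missing every locus are excluded with a warning.
#'
#' @param genotypes long data frame `individual_id, locus, allele1,
#'   allele2`.
#' @return centered numeric matrix (rows = individuals, columns =
#'   `locus.allele`), with attributes `"raw"` (uncentered counts with
#'   `NA` for missing loci) and `"col_means"`.
#' @export
genotype_matrix <- function(genotypes) {
  ids <- sort(unique(genotypes$individual_id))
  loci <- sort(unique(genotypes$locus))
  cols <- list()
  for (l in loci) {
    g <- genotypes[genotypes$locus == l, , drop = FALSE]
    alleles <- sort(unique(stats::na.omit(c(g$allele1, g$allele2))))
    for (a in alleles) {
      cnt <- rep(NA_real_, length(ids))
      m <- match(g$individual_id, ids)
      cnt[m] <- ifelse(is.na(g$allele1), NA_real_,
                       (g$allele1 == a) + (g$allele2 == a))
      cols[[paste(l, a, sep = ".")]] <- cnt
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- ids
  all_missing <- rowSums(!is.na(X)) == 0
  if (any(all_missing)) {
    warning("excluding individuals with no typed locus: ",
            paste(ids[all_missing], collapse = ", "))
    X <- X[!all_missing, , drop = FALSE]
  }
  raw <- X
  mu <- colMeans(X, na.rm = TRUE)
  for (k in seq_len(ncol(X))) X[is.na(X[, k]), k] <- mu[k]
  Xc <- sweep(X, 2, mu)
  attr(Xc, "raw") <- raw
  attr(Xc, "col_means") <- mu
  Xc
}

#' PCA-based species assignment against a labeled reference panel
#'
#' Projects reference-panel and query genotypes jointly onto principal
#' components of the allele-count matrix, computes species centroids on
#' the first two axes from the labeled reference rows, and assigns each
#' query to the nearest centroid (Euclidean distance on PC1-PC2). This
#' mechanizes the visual reading of a two-species PCA; admixture-model
#' cross-checks are deliberately out of scope.
#'
#' @param panel long genotype data frame of the reference panel
#'   (`individual_id, locus, allele1, allele2`).
#' @param panel_species named character vector: species label per panel
#'   individual (levels with fewer than `min_per_class` members are
#'   dropped from centroid construction).
#' @param queries long genotype data frame of the monitoring individuals
#'   to assign (same locus panel).
#' @param n_axes number of retained axes in the output (>= 2).
#' @param min_per_class minimum labeled members per species class.
#' @return object of class `assignment_result`: `coords` (PC coordinates
#'   with a `role` column), `variance_explained`, `centroids`,
#'   `assignments` (query, nearest-centroid label, centroid distances).
#' @export
pca_assign <- function(panel, panel_species, queries, n_axes = 2,
                       min_per_class = 5) {
  stopifnot(n_axes >= 2)
  panel$individual_id <- paste0("ref:", panel$individual_id)
  names(panel_species) <- paste0("ref:", names(panel_species))
  joint <- rbind(panel[, c("individual_id", "locus", "allele1", "allele2")],
                 queries[, c("individual_id", "locus", "allele1", "allele2")])
  X <- genotype_matrix(joint)

  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  varex <- pc$sdev^2 / sum(pc$sdev^2)
  n_axes <- min(n_axes, ncol(pc$x))
  if (n_axes < 2) stop("fewer than 2 informative axes")
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]

  is_ref <- rownames(scores) %in% names(panel_species)
  labels <- panel_species[rownames(scores)[is_ref]]
  keep_classes <- names(which(table(labels[!is.na(labels)]) >= min_per_class))
  if (length(keep_classes) < 2) {
    stop("need >= 2 species classes with >= ", min_per_class,
         " labeled members")
  }
  cent <- t(vapply(keep_classes, function(cl) {
    colMeans(scores[is_ref, 1:2, drop = FALSE][
      !is.na(labels) & labels == cl, , drop = FALSE])
  }, numeric(2)))

  qrows <- which(!is_ref)
  d <- matrix(NA_real_, length(qrows), length(keep_classes),
              dimnames = list(rownames(scores)[qrows], keep_classes))
  for (k in seq_along(keep_classes)) {
    d[, k] <- sqrt((scores[qrows, 1] - cent[k, 1])^2 +
                     (scores[qrows, 2] - cent[k, 2])^2)
  }
  assignments <- data.frame(
    individual_id = rownames(d),
    species = keep_classes[apply(d, 1, which.min)],
    stringsAsFactors = FALSE)
  assignments <- cbind(assignments,
                       stats::setNames(as.data.frame(d),
                                       paste0("dist_", keep_classes)))
  rownames(assignments) <- NULL

  coords <- data.frame(individual_id = sub("^ref:", "", rownames(scores)),
                       role = ifelse(is_ref, "reference", "query"),
                       species = NA_character_,
                       stringsAsFactors = FALSE)
  coords$species[is_ref] <- unname(labels)
  coords <- cbind(coords, as.data.frame(scores))
  rownames(coords) <- NULL

  out <- list(coords = coords, variance_explained = varex[seq_len(n_axes)],
              centroids = cent, assignments = assignments)
  class(out) <- "assignment_result"
  out
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf(
    "PCA species assignment: %d queries vs %d reference genotypes; PC1-2 explain %.1f%% of variance\n",
    nrow(x$assignments), sum(x$coords$role == "reference"),
    100 * sum(x$variance_explained[1:2])))
  print(table(x$assignments$species))
  invisible(x)
}

#' Scatter plot of the assignment PCA
#'
#' @param x an `assignment_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.assignment_result <- function(x, ...) {
  ref <- x$coords$role == "reference"
  cls <- factor(x$coords$species)
  col <- ifelse(ref, as.integer(cls) + 1L, 1L)
  graphics::plot(x$coords$PC1, x$coords$PC2,
                 pch = ifelse(ref, 17, 1), col = col,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$variance_explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$variance_explained[2]),
                 ...)
  graphics::points(x$centroids, pch = 8, cex = 2,
                   col = seq_len(nrow(x$centroids)) + 1L)
  graphics::legend("topright", legend = rownames(x$centroids),
                   col = seq_len(nrow(x$centroids)) + 1L, pch = 17, bty = "n")
  invisible(x)
}
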