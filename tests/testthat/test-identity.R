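# Genotype distance, individual clustering, sex resolution, histories

gt <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(locus = sprintf("L%d", seq_len(nrow(m))),
             allele1 = m[, 1], allele2 = m[, 2])
}

test_that("mismatch distance uses maximal allele pairing and skips missing loci", {
  a <- gt(1, 2, 3, 3, 5, 6)
  expect_equal(genotype_distance(a, a)$mismatches, 0)
  b <- gt(1, 4, 3, 3, 5, 6)          # A/B vs A/C at L1
  expect_equal(genotype_distance(a, b)$mismatches, 1)
  d <- gt(7, 8, 3, 3, 5, 6)          # A/B vs C/D at L1
  expect_equal(genotype_distance(a, d)$mismatches, 2)
  # order within the pair does not matter
  e <- gt(2, 1, 3, 3, 6, 5)
  expect_equal(genotype_distance(a, e)$mismatches, 0)
  # missing locus skipped
  f <- gt(NA, NA, 3, 3, 5, 6)
  r <- genotype_distance(a, f)
  expect_equal(r$mismatches, 0)
  expect_equal(r$compared_loci, 2)
  # no comparable loci -> undefined
  g <- gt(NA, NA, NA, NA, NA, NA)
  expect_true(is.na(genotype_distance(a, g)$mismatches))
  # pattern loci weigh 2 per differing class
  r2 <- genotype_distance(a, a, p1 = c(Sat2 = "x"), p2 = c(Sat2 = "y"))
  expect_equal(r2$mismatches, 2)
  expect_equal(genotype_distance(a, a, p1 = c(Sat2 = "x"),
                                 p2 = c(Sat2 = "x"))$mismatches, 0)
})

make_consensus <- function(genos, sexes, sessions = NULL, days = NULL,
                           methods = NULL, patterns = NULL) {
  n <- length(genos)
  if (is.null(sessions)) sessions <- rep("pso01", n)
  if (is.null(days)) days <- rep(1L, n)
  if (is.null(methods)) methods <- rep("systematic", n)
  ids <- sprintf("s%02d", seq_len(n))
  calls <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(sample_id = ids[i], genos[[i]])
  }))
  structure(list(
    samples = data.frame(sample_id = ids, session = sessions, day = days,
                         method = methods, sex = sexes,
                         n_scored = vapply(genos, function(g)
                           sum(!is.na(g$allele1)), integer(1)),
                         accepted = TRUE, stringsAsFactors = FALSE),
    calls = calls, loci = unique(calls$locus), min_loci = 0,
    patterns = patterns), class = "consensus_set")
}

seven <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  stopifnot(nrow(m) == 7)
  data.frame(locus = sprintf("L%d", 1:7), allele1 = m[, 1], allele2 = m[, 2])
}
base_g <- seven(1, 2, 3, 3, 5, 6, 7, 7, 9, 9, 11, 12, 13, 14)

test_that("clustering merges within the mismatch threshold and not beyond", {
  g_same <- base_g
  g_2mm <- base_g; g_2mm$allele1[1] <- 15; g_2mm$allele2[1] <- 16  # 2 mismatches
  g_3mm <- g_2mm; g_3mm$allele1[2] <- 17                           # 3 mismatches
  cons <- make_consensus(list(base_g, g_same, g_3mm),
                         sexes = c("F", "F", "F"))
  inds <- cluster_individuals(cons)
  expect_equal(nrow(inds$individuals), 2)
  cons2 <- make_consensus(list(base_g, g_2mm), sexes = c("F", "F"))
  inds2 <- cluster_individuals(cons2)
  expect_equal(nrow(inds2$individuals), 1)
  expect_equal(nrow(inds2$borderline), 1)
  # max_mismatch = 0 separates them again; count non-increasing in threshold
  expect_equal(nrow(cluster_individuals(cons2, max_mismatch = 0)$individuals), 2)
  # sparse genotypes (< min_shared_loci comparable) never merge
  g_sparse <- base_g
  g_sparse$allele1[1:4] <- NA; g_sparse$allele2[1:4] <- NA
  cons3 <- make_consensus(list(base_g, g_sparse), sexes = c("F", "F"))
  expect_equal(nrow(cluster_individuals(cons3)$individuals), 2)
  # pattern loci resolve otherwise identical genotypes
  pat <- data.frame(sample_id = c("s01", "s02"), locus = "Sat2",
                    class = c("a", "b"))
  cons4 <- make_consensus(list(base_g, base_g), sexes = c("F", "F"),
                          patterns = pat)
  expect_equal(nrow(cluster_individuals(cons4, max_mismatch = 1)$individuals), 2)
})

test_that("clustering is invariant to input row order", {
  set.seed(9)
  genos <- list(base_g, base_g,
                within(base_g, allele1[3] <- 20),
                within(base_g, {allele1[1] <- 30; allele1[2] <- 30;
                                allele2[4] <- 31}))
  sexes <- c("F", "M", "F", "F")
  cons <- make_consensus(genos, sexes)
  ref <- cluster_individuals(cons)
  for (i in 1:5) {
    perm <- sample(4)
    consp <- cons
    consp$samples <- cons$samples[perm, ]
    consp$calls <- cons$calls[sample(nrow(cons$calls)), ]
    got <- cluster_individuals(consp)
    expect_equal(got$individuals, ref$individuals)
    expect_equal(got$members[order(got$members$sample_id), ],
                 ref$members[order(ref$members$sample_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("false females are reclassified inside male genotype groups", {
  cons <- make_consensus(list(base_g, base_g, base_g), c("M", "F", "F"))
  inds <- cluster_individuals(cons)
  expect_equal(nrow(inds$individuals), 1)
  expect_equal(inds$individuals$sex, "M")
  expect_equal(inds$individuals$n_false_female, 2)
  consF <- make_consensus(list(base_g, base_g), c("F", "F"))
  indsF <- cluster_individuals(consF)
  expect_equal(indsF$individuals$sex, "F")
  expect_equal(indsF$individuals$n_false_female, 0)
})

test_that("sex-marker dropout produces false females at the expected rate", {
  cfg <- errorfree_config(31, n_females = 0, n_males = 60, n_pso = 2)
  cfg$sry_dropout <- 0.3
  sim <- simulate_dataset(cfg)
  cons <- call_consensus(sim$replicates)
  # all-male population: every female-called sample is a dropout artifact
  p_ff <- 0.3 ^ cfg$n_replicates
  n <- nrow(cons$samples)
  obs <- sum(cons$samples$sex == "F")
  expect_lt(abs(obs - n * p_ff), 3 * sqrt(n * p_ff * (1 - p_ff)) + 1)
  inds <- cluster_individuals(cons, calendar = sim$truth$calendar)
  expect_equal(sum(inds$individuals$n_false_female), obs)
  expect_true(all(inds$individuals$sex == "M"))
})

test_that("error-free simulation is recovered exactly: clusters, sexes, histories", {
  cfg <- errorfree_config(55, n_females = 25, n_males = 25, n_pso = 4,
                          p = 0.4)
  sim <- simulate_dataset(cfg)
  st <- attr(sim$replicates, "sample_truth")
  expect_gte(nrow(st), 300)
  cons <- call_consensus(sim$replicates)
  inds <- cluster_individuals(cons, calendar = sim$truth$calendar)
  detected <- unique(st$individual_id)
  expect_equal(nrow(inds$individuals), length(detected))
  # membership equals ground truth
  map <- merge(inds$members, st, by = "sample_id")
  expect_true(all(tapply(map$individual_id.y, map$individual_id.x,
                         function(z) length(unique(z)) == 1)))
  # sexes equal ground truth
  sex_true <- stats::setNames(sim$truth$individuals$sex,
                              sim$truth$individuals$individual_id)
  one <- map[!duplicated(map$individual_id.x), ]
  expect_equal(unname(sex_true[one$individual_id.y]),
               inds$individuals$sex[match(one$individual_id.x,
                                          inds$individuals$individual_id)])
  # histories equal ground truth
  h <- build_histories(inds, sim$truth$calendar)
  ht <- simulated_histories(sim$truth, observed = FALSE)
  expect_equal(sum(h$det, na.rm = TRUE), sum(ht$det, na.rm = TRUE))
  expect_equal(dim(h$det), dim(ht$det))
  # conservation: detections = (individual, session, day) combos sampled
  expect_equal(sum(h$det, na.rm = TRUE),
               nrow(unique(st[, c("individual_id", "pso", "sso")])))
})

test_that("history building indexes days correctly and filters systematic samples", {
  g_other <- within(base_g, {allele1[1] <- 20; allele1[2] <- 21
                             allele2[4] <- 22})
  cons <- make_consensus(
    list(base_g, base_g, g_other),
    sexes = c("M", "M", "F"),
    sessions = c("pso01", "pso01", "pso01"),
    days = c(2L, 5L, 3L),
    methods = c("systematic", "opportunistic", "opportunistic"))
  inds <- cluster_individuals(cons, calendar = data.frame(
    session = "pso01", pso = 1, season = "spring", n_days = 6))
  cal <- data.frame(session = "pso01", pso = 1, season = "spring", n_days = 6)
  h <- build_histories(inds, cal)
  expect_equal(as.vector(h$det[1, 1, ]), c(0, 1, 0, 0, 1, 0))
  hs <- build_histories(inds, cal, systematic_only = TRUE)
  expect_equal(dim(hs$det)[1], 1)  # opportunistic-only individuals drop out
  expect_equal(as.vector(hs$det[1, 1, ]), c(0, 1, 0, 0, 0, 0))
  # unknown session label is a hard error
  bad <- inds; bad$members$session[1] <- "nope"
  expect_error(build_histories(bad, cal), "unknown session")
  # MARK-style export round-trips the detection string
  tmp <- tempfile(fileext = ".inp")
  write_inp(h, tmp)
  lines <- readLines(tmp)
  expect_length(lines, 2)
  expect_match(lines[1], "010010 0 1;$")
})
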