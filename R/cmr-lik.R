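# Likelihood machinery for the robust-design model with misidentification.
#
# The joint log-likelihood is a composite of three pieces, evaluated per
# sex group:
#
# (i) Within-primary-occasion emission probabilities. For an on-site animal
#     the recorded detection pattern over the K secondary occasions follows
#     a thinned capture process: captures occur with probability p (before
#     the first true capture of the session) or c (after), and each capture
#     is recorded under the animal's own genotype with probability alpha;
#     a misrecorded capture leaves no detection and spawns a ghost. A
#     two-state forward recursion over occasions (state = truly captured
#     before or not) yields q(w), the probability of recorded pattern w,
#     and the per-occasion expected ghost spawn rate g_j per on-site animal.
#
# (ii) Open component. Each observed genotype with >= 2 total detections is
#     a true individual; from its first detection session onward its state
#     (on-site, temporary emigrant, dead) evolves as a hidden Markov chain
#     with survival phi and Markovian emigration gamma''/gamma', emitting
#     q_t(w_t) when on-site and an empty pattern otherwise. Sessions before
#     first detection contribute nothing (entry is not modeled).
#
# The information structure mirrors CJS conditioning: an animal's first
# detection session contributes its within-session pattern conditional on
# detection; later sessions contribute unconditional emissions (detection
# Bernoulli x pattern when detected, q0 for an on-site gap), which is what
# identifies p/c across sessions; the per-session count term supplies f0.
#
# (iii) Ghost mixture and undetected count. Genotypes detected exactly once
#     in the whole study are a mixture of once-caught real animals and
#     ghosts. Ghost counts per occasion are modeled as Poisson with
#     intensity N_t * g_j (N_t = real on-site animals). The number k of
#     real animals among the s singletons of a session is marginalized
#     exactly (elementary symmetric polynomial recursion), jointly with the
#     per-session binomial term binom(C + k + f0, f0) * q0^f0 that carries
#     the undetected count f0 (q0 = probability an on-site animal is
#     recorded undetected). With alpha = 1 the ghost intensity vanishes and
#     the likelihood reduces, session by session, to the standard closed
#     full likelihood inside the standard robust design.

# ---- data preparation --------------------------------------------------

.rd_prep <- function(histories) {
  stopifnot(inherits(histories, "capture_histories"))
  det <- histories$det
  n_all <- dim(det)[1]
  T <- dim(det)[2]
  if (n_all == 0) stop("capture histories contain zero detections")
  groups <- sort(unique(unname(histories$group)))
  total <- apply(det, 1, sum, na.rm = TRUE)
  if (any(total == 0)) stop("histories with zero detections are invalid")

  prep_g <- list()
  for (g in groups) {
    rows <- which(unname(histories$group) == g)
    sub <- det[rows, , , drop = FALSE]
    tot <- total[rows]
    singleton <- tot == 1
    # certain-real block
    cr <- which(!singleton)
    W <- lapply(seq_len(T), function(t) {
      m <- sub[cr, t, seq_len(histories$sso_counts[t]), drop = FALSE]
      m <- array(m, dim = dim(m)[c(1, 3)])
      m[is.na(m)] <- 0L
      m
    })
    det_at <- vapply(seq_len(T), function(t) rowSums(W[[t]]) > 0,
                     logical(length(cr)))
    det_at <- matrix(det_at, nrow = length(cr))
    t1 <- apply(det_at, 1, function(z) which(z)[1])
    Ct <- colSums(det_at)
    C1t <- tabulate(t1, nbins = T)     # certain-real first detected at t
    # singleton block: session and occasion of the single detection
    sg <- which(singleton)
    sing <- if (length(sg)) {
      pos <- t(vapply(sg, function(i) {
        m <- matrix(sub[i, , ], nrow = T)
        w <- which(m == 1, arr.ind = TRUE)
        c(w[1, 1], w[1, 2])
      }, numeric(2)))
      data.frame(t = pos[, 1], j = pos[, 2])
    } else data.frame(t = integer(0), j = integer(0))
    prep_g[[g]] <- list(W = W, t1 = t1, det_at = det_at, Ct = Ct, C1t = C1t,
                        n_cert = length(cr), sing = sing)
  }
  list(groups = groups, T = T, K = histories$sso_counts,
       seasons = histories$seasons, per_group = prep_g,
       n_detections = sum(total), n_histories = n_all)
}

# ---- emission recursions ----------------------------------------------

# q(w) for each row of pattern matrix W (n x K), plus q(empty) and the
# per-occasion expected ghost spawn rate per on-site animal.
.rd_emission <- function(W, p, c_, alpha) {
  n <- nrow(W)
  K <- length(p)
  a0 <- rep(1, n); a1 <- rep(0, n)
  e0 <- 1; e1 <- 0                     # empty-pattern recursion
  b0 <- 1; b1 <- 0                     # unconditional state occupancy
  gj <- numeric(K)
  for (j in seq_len(K)) {
    pa <- p[j] * alpha; ca <- c_[j] * alpha
    if (n > 0) {
      d <- W[, j]
      nd <- 1 - d
      a1n <- d * (a0 * pa + a1 * ca) +
        nd * (a0 * p[j] * (1 - alpha) + a1 * (1 - ca))
      a0 <- nd * a0 * (1 - p[j])
      a1 <- a1n
    }
    e1n <- e0 * p[j] * (1 - alpha) + e1 * (1 - ca)
    e0 <- e0 * (1 - p[j])
    e1 <- e1n
    gj[j] <- (b0 * p[j] + b1 * c_[j]) * (1 - alpha)
    b1 <- b1 + b0 * p[j]
    b0 <- 1 - b1
  }
  list(q = if (n > 0) a0 + a1 else numeric(0), q0 = e0 + e1, gj = gj)
}

# 3-state transition matrix (on-site, off-site, dead) for one interval
.rd_transition <- function(phi, gdp, gp) {
  rbind(c(phi * (1 - gdp), phi * gdp, 1 - phi),
        c(phi * (1 - gp), phi * gp, 1 - phi),
        c(0, 0, 1))
}

# ---- log-likelihood ----------------------------------------------------

.rd_loglik <- function(par, prep, pm, diagnostics = FALSE, units = FALSE) {
  T <- prep$T
  ll <- 0
  unit_ll <- numeric(0)   # per-history / per-cell contributions (sandwich)
  diag_rows <- list()
  for (g in prep$groups) {
    pg <- prep$per_group[[g]]
    # per-session emission quantities
    em <- vector("list", T)
    pcs <- vector("list", T)
    f0t <- numeric(T)
    alph <- numeric(T)
    memo <- new.env(parent = emptyenv())
    for (t in seq_len(T)) {
      season <- prep$seasons[t]
      key <- paste(season, prep$K[t])
      if (is.null(memo[[key]])) {
        memo[[key]] <- list(
          pc = .rd_pc_vectors(pm, par, g, season, prep$K[t]),
          alpha = .rd_value(pm, par, "alpha", g, season),
          f0 = .rd_value(pm, par, "f0", g, season))
      }
      pcs[[t]] <- memo[[key]]$pc
      alph[t] <- memo[[key]]$alpha
      f0t[t] <- memo[[key]]$f0
      em[[t]] <- .rd_emission(pg$W[[t]], pcs[[t]]$p, pcs[[t]]$c, alph[t])
    }
    phi <- .rd_value(pm, par, "phi", g, NA)
    gdp <- .rd_value(pm, par, "gamma_dprime", g, NA)
    gp <- .rd_value(pm, par, "gamma_prime", g, NA)
    M <- .rd_transition(phi, gdp, gp)

    # (ii) open HMM over certain-real histories, from first detection on.
    # Emissions are conditional on the session-level detection indicator:
    # detected & on-site -> q(w)/(1-q0) (within-session pattern), gap &
    # on-site -> q0, gap & off-site/dead -> 1. The session-level detection
    # Bernoulli of every detected animal is carried once, by the
    # undetected-count term (iii).
    if (pg$n_cert > 0) {
      n <- pg$n_cert
      F <- matrix(0, n, 3)
      lli <- numeric(n)
      for (t in seq_len(T)) {
        starting <- pg$t1 == t
        active <- pg$t1 < t
        pstar <- 1 - em[[t]]$q0
        if (any(active)) {
          F[active, ] <- F[active, , drop = FALSE] %*% M
          det_t <- pg$det_at[active, t]
          emis <- cbind(em[[t]]$q[active], !det_t, !det_t)
          F[active, ] <- F[active, , drop = FALSE] * emis
          sc <- rowSums(F[active, , drop = FALSE])
          lli[active] <- lli[active] + log(sc)
          F[active, ] <- F[active, , drop = FALSE] / sc
        }
        if (any(starting)) {
          F[starting, ] <- 0
          F[starting, 1] <- 1
          lli[starting] <- lli[starting] + log(em[[t]]$q[starting] / pstar)
        }
      }
      ll <- ll + sum(lli)
      if (units) unit_ll <- c(unit_ll, lli)
    }

    # forward-tail probabilities w_t = P(no detection after t | on-site at t)
    wtail <- numeric(T)
    wvec <- c(1, 1, 1)
    wtail[T] <- 1
    if (T > 1) {
      for (t in (T - 1):1) {
        etail <- c(em[[t + 1]]$q0, 1, 1)
        wvec <- as.vector(M %*% (etail * wvec))
        wtail[t] <- wvec[1]
      }
    }

    # (iii) singleton mixture + undetected-count term, per session
    for (t in seq_len(T)) {
      season <- prep$seasons[t]
      pc <- pcs[[t]]
      sj <- pg$sing$j[pg$sing$t == t]
      s <- length(sj)
      C <- pg$Ct[t]
      f0 <- f0t[t]
      q0 <- em[[t]]$q0
      gj <- em[[t]]$gj
      Gtot <- sum(gj)
      # undetected-count term: full closed-population count likelihood for
      # session t (D of C+k+f0 on-site animals detected, each with prob
      # 1-q0), with the Stirling (Poisson-population) form of the binomial
      # coefficient so closed-population MLEs coincide with the classical
      # Darroch / Lincoln-Petersen estimators. At its f0-profile this term
      # is exactly zero, so it supplies the undetected count without
      # adding detection information already carried by the open HMM.
      xlx <- function(z) ifelse(z > 0, z * log(z), 0)
      ks <- 0:s
      D <- C + ks
      logBv <- xlx(D + f0) - xlx(f0) - xlx(D) + f0 * log(q0) +
        D * log1p(-q0)
      if (s > 0) {
        qs <- .rd_emission(diag(prep$K[t])[sj, , drop = FALSE],
                           pc$p, pc$c, alph[t])$q
        Lreal <- qs / (1 - q0) * wtail[t]
      } else {
        Lreal <- numeric(0)
      }
      if (Gtot < 1e-12) {
        # no ghosts possible: all singletons real
        cell_ll <- sum(log(Lreal)) + logBv[s + 1]
        ll <- ll + cell_ll
        if (units) unit_ll <- c(unit_ll, cell_ll)
        Ek <- s
      } else {
        # exact marginal over k = number of real singletons
        x <- Lreal / gj[sj]
        m <- max(x, 1)
        esp <- c(1, rep(0, s))           # scaled elementary symmetric polys
        for (v in x / m) {
          if (s > 0) esp[2:(s + 1)] <- esp[2:(s + 1)] + v * esp[1:s]
        }
        logesp <- log(esp) + ks * log(m)
        Nk <- C + ks + f0
        logterm <- sum(log(gj[sj])) + (s - ks) * log(pmax(Nk, 1e-12)) +
          logesp - Nk * Gtot + logBv
        mx <- max(logterm)
        cell_ll <- mx + log(sum(exp(logterm - mx)))
        ll <- ll + cell_ll
        if (units) unit_ll <- c(unit_ll, cell_ll)
        post <- exp(logterm - mx); post <- post / sum(post)
        Ek <- sum(ks * post)
      }
      if (diagnostics) {
        diag_rows[[length(diag_rows) + 1]] <- data.frame(
          group = g, pso = t, season = season, C = C, s_singletons = s,
          E_real_singletons = Ek, f0 = f0, q_empty = q0,
          p_star = 1 - q0, alpha = alph[t], stringsAsFactors = FALSE)
      }
    }
  }
  if (diagnostics) {
    attr(ll, "cells") <- do.call(rbind, diag_rows)
  }
  if (units) attr(ll, "units") <- unit_ll
  ll
}

#' Negative log-likelihood of the robust-design misidentification model
#'
#' Evaluates the composite likelihood described in the package vignette for
#' a link-scale parameter vector: within-session closed misidentification
#' components (capture `p`, recapture `c`, correct-identification `alpha`,
#' undetected count `f0`, Poisson ghost intensities, exact marginalization
#' of the real-vs-ghost split of single-detection genotypes) joined to an
#' open three-state hidden Markov chain (survival `phi`, Markovian
#' temporary emigration `gamma''`/`gamma'`) evaluated by forward recursion.
#'
#' @param par numeric vector of link-scale parameters (order as in
#'   `rd_par_names()` for the model/data combination; logit for
#'   probabilities, log for `f0`).
#' @param histories a [build_histories()] result.
#' @param model an [rd_model()] structure.
#' @return the negative log-likelihood (penalized `1e10` when non-finite).
#' @export
rd_negloglik <- function(par, histories, model = rd_model()) {
  prep <- .rd_prep(histories)
  pm <- .rd_parmap(model, prep$groups, prep$seasons, max(prep$K))
  stopifnot(length(par) == pm$K)
  ll <- .rd_loglik(par, prep, pm)
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' @rdname rd_negloglik
#' @export
rd_par_names <- function(histories, model = rd_model()) {
  prep <- .rd_prep(histories)
  .rd_parmap(model, prep$groups, prep$seasons, max(prep$K))$par_names
}
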