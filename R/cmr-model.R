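#' Mark a robust-design parameter family as fixed
#'
#' @param value the real-scale value the family is pinned to (e.g.
#'   `gamma_prime = rd_fixed(1), gamma_dprime = rd_fixed(0)` is the
#'   no-movement constraint; `alpha = rd_fixed(1)` disables
#'   misidentification).
#' @return an object of class `rd_fixed`.
#' @export
rd_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, value >= 0)
  structure(list(value = value), class = "rd_fixed")
}

#' Robust-design model structure
#'
#' Declares, per parameter family, how the parameter varies: `"constant"`,
#' `"sex"`, `"season"`, `"sex_season"`, `"occasion"` (secondary-occasion
#' index; `p`/`c` only), `"equal_p"` (`c` only: no behavioural response,
#' `c` identical to `p`), or [rd_fixed()]. Probabilities live on the logit
#' link, the undetected-count `f0` on the log link.
#'
#' Families: apparent survival `phi` and Markovian temporary-emigration
#' rates `gamma_prime` (stay off-site) / `gamma_dprime` (leave site) act
#' between primary occasions; capture `p` and recapture `c` act per
#' secondary occasion; correct-identification probability `alpha` and
#' undetected count `f0` act per primary occasion and group.
#'
#' @param phi,gamma_prime,gamma_dprime,p,c,alpha,f0 structure strings or
#'   [rd_fixed()] values.
#' @return object of class `rd_model`.
#' @export
#' @examples
#' rd_model(phi = "sex", p = "season", c = "season",
#'          alpha = "season", f0 = "season")
rd_model <- function(phi = "constant",
                     gamma_prime = "constant",
                     gamma_dprime = "constant",
                     p = "constant",
                     c = "constant",
                     alpha = "constant",
                     f0 = "constant") {
  spec <- list(phi = phi, gamma_prime = gamma_prime,
               gamma_dprime = gamma_dprime, p = p, c = c,
               alpha = alpha, f0 = f0)
  allowed <- list(
    phi = c("constant", "sex"),
    gamma_prime = c("constant", "sex"),
    gamma_dprime = c("constant", "sex"),
    p = c("constant", "sex", "season", "sex_season", "occasion"),
    c = c("constant", "sex", "season", "sex_season", "occasion", "equal_p"),
    alpha = c("constant", "sex", "season", "sex_season"),
    f0 = c("constant", "sex", "season", "sex_season"))
  for (fam in names(spec)) {
    s <- spec[[fam]]
    if (inherits(s, "rd_fixed")) {
      if (fam != "f0" && s$value > 1) {
        stop(fam, " is a probability; fixed value must lie in [0,1]")
      }
      next
    }
    if (!is.character(s) || length(s) != 1 || !(s %in% allowed[[fam]])) {
      stop("invalid structure for ", fam, ": must be one of ",
           paste(allowed[[fam]], collapse = ", "), " or rd_fixed()")
    }
  }
  structure(spec, class = "rd_model")
}

#' @export
print.rd_model <- function(x, ...) {
  lab <- vapply(names(x), function(f) {
    s <- x[[f]]
    if (inherits(s, "rd_fixed")) sprintf("%s = %g", f, s$value)
    else sprintf("%s(%s)", f, switch(s, constant = ".", sex = "sex",
                                     season = "season",
                                     sex_season = "sex, season",
                                     occasion = "occ", equal_p = "= p"))
  }, character(1))
  cat("Robust-design misidentification model:", paste(lab, collapse = ", "),
      "\n")
  invisible(x)
}

# level label of a family's parameter for (group g, season, occasion j)
.rd_level <- function(structure, g, season, j = NULL) {
  switch(structure,
         constant = "(.)",
         sex = g,
         season = season,
         sex_season = paste(g, season, sep = ","),
         occasion = sprintf("occ%d", j),
         stop("unresolvable structure: ", structure))
}

# Build the link-scale parameter map for a model on given data dimensions.
# Returns: $par_names, $K, and $index(fam, g, season, j) -> index (>0),
# 0 = fixed (value in $fixed[[fam]]), -1 = c tied to p.
.rd_parmap <- function(model, groups, seasons, max_occ) {
  par_names <- character(0)
  idx <- list()
  fixed <- list()
  for (fam in names(model)) {
    s <- model[[fam]]
    if (inherits(s, "rd_fixed")) {
      fixed[[fam]] <- s$value
      next
    }
    if (identical(s, "equal_p")) next
    levels <- switch(s,
      constant = "(.)",
      sex = groups,
      season = unique(seasons),
      sex_season = as.vector(outer(groups, unique(seasons), paste, sep = ",")),
      occasion = sprintf("occ%d", seq_len(max_occ)))
    names_fam <- paste0(fam, "[", levels, "]")
    idx[[fam]] <- stats::setNames(length(par_names) + seq_along(levels),
                                  levels)
    par_names <- c(par_names, names_fam)
  }
  links <- stats::setNames(rep("logit", length(par_names)), par_names)
  links[grepl("^f0\\[", par_names)] <- "log"
  list(par_names = par_names, K = length(par_names), idx = idx,
       fixed = fixed, links = links, model = model,
       groups = groups, seasons = seasons, max_occ = max_occ)
}

# Real-scale value of family `fam` for cell (g, season, occasion j)
# given the link-scale parameter vector.
.rd_value <- function(pm, par, fam, g, season, j = NULL) {
  s <- pm$model[[fam]]
  if (inherits(s, "rd_fixed")) return(s$value)
  if (identical(s, "equal_p")) return(.rd_value(pm, par, "p", g, season, j))
  lev <- .rd_level(s, g, season, j)
  k <- pm$idx[[fam]][[lev]]
  x <- par[k]
  if (fam == "f0") exp(x) else stats::plogis(x)
}

# per-occasion vectors of p and c for (group, PSO with given season, K occ)
.rd_pc_vectors <- function(pm, par, g, season, K) {
  one <- function(fam) {
    s <- pm$model[[fam]]
    if (identical(s, "equal_p")) return(one("p"))
    if (identical(s, "occasion")) {
      return(stats::plogis(par[pm$idx[[fam]][sprintf("occ%d", seq_len(K))]]))
    }
    rep(.rd_value(pm, par, fam, g, season), K)
  }
  list(p = one("p"), c = one("c"))
}
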