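# Participant-level pseudo-bulk differential abundance with empirical-Bayes
# variance moderation and composite fold-change/p-value (pi) significance.

#' Pseudo-bulk participant medians
#'
#' Downsamples single-fibre data to one median log2 value per protein per
#' (participant, group) cell. Fibres with `NA` group are excluded (e.g.
#' hybrid fibres in a pure-subtype contrast).
#'
#' @param pm a log2-scale `protein_matrix`.
#' @param grouping named character vector mapping fibre ids to group labels;
#'   fibres absent or mapped to `NA` are ignored.
#' @return A `pseudobulk` object: `values` (proteins x cells), `cells`
#'   (data frame `participant`, `group`, `n_fibres`) and `counts` (fibres
#'   aggregated per protein per cell).
#' @export
pseudobulk_median <- function(pm, grouping) {
  if (!pm$log2) stop_invalid("pseudo-bulk aggregation expects the log2-scale matrix")
  grouping <- grouping[!is.na(grouping)]
  grouping <- grouping[names(grouping) %in% colnames(pm$values)]
  if (!length(grouping)) stop_invalid("empty grouping")
  ann <- pm$annotations
  part <- ann$participant[match(names(grouping), ann$fibre_id)]
  key <- paste(part, grouping, sep = "||")
  cells <- unique(data.frame(participant = part, group = unname(grouping),
                             key = key, stringsAsFactors = FALSE))
  cells <- cells[order(cells$group, cells$participant), , drop = FALSE]
  vals <- matrix(NA_real_, nrow(pm$values), nrow(cells),
                 dimnames = list(rownames(pm$values),
                                 paste(cells$participant, cells$group, sep = ".")))
  counts <- vals
  for (i in seq_len(nrow(cells))) {
    fibres <- names(grouping)[key == cells$key[i]]
    sub <- pm$values[, fibres, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- apply(sub, 1, stats::median, na.rm = TRUE)
    m[n == 0] <- NA_real_
    vals[, i] <- m
    counts[, i] <- n
  }
  cells$n_fibres <- vapply(cells$key, function(k) sum(key == k), 1L)
  cells$key <- NULL
  rownames(cells) <- colnames(vals)
  structure(list(values = vals, cells = cells, counts = counts),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk> %d proteins x %d (participant, group) cells\n",
              nrow(x$values), ncol(x$values)))
  print(x$cells)
  invisible(x)
}

#' Quantile normalisation tolerating missing values
#'
#' Classical quantile normalisation computed on the complete rows (rows with
#' no missing value): each column's sorted complete-row values are replaced
#' by the cross-column means of sorted values, so afterwards all columns
#' share an identical multiset over complete rows. Ties within a column
#' receive the mean of their target quantiles. Entries in rows with missing
#' values are normalised by interpolating the reference distribution at the
#' value's rank within its column's complete-row values, which preserves
#' within-column rank order throughout.
#'
#' @param x numeric matrix or `pseudobulk` object (>= 2 columns; a single
#'   column is returned unchanged with a warning).
#' @return Object of the same type, normalised.
#' @export
quantile_normalise <- function(x) {
  if (inherits(x, "pseudobulk")) {
    x$values <- quantile_normalise(x$values)
    return(x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) {
    warning("single column: quantile normalisation is the identity", call. = FALSE)
    return(x)
  }
  complete <- !apply(is.na(x), 1, any)
  if (sum(complete) < 2L)
    stop_invalid("insufficient data: need at least 2 complete rows")
  comp <- x[complete, , drop = FALSE]
  sorted <- apply(comp, 2, sort)
  ref <- rowMeans(sorted)              # reference distribution
  m <- length(ref)
  csum0 <- c(0, cumsum(ref))           # zero-padded for tied-block means
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- comp[, j]
    rmin <- rank(v, ties.method = "min")
    rmax <- rank(v, ties.method = "max")
    # tied blocks get the mean of their target quantiles
    newv <- (csum0[rmax + 1] - csum0[rmin]) / (rmax - rmin + 1)
    out[complete, j] <- newv
    inc <- which(!complete & !is.na(x[, j]))
    if (length(inc)) {
      sv <- sorted[, j]
      pos <- stats::approx(sv, seq_len(m), xout = x[inc, j], rule = 2,
                           ties = "ordered")$y
      out[inc, j] <- stats::approx(seq_len(m), ref, xout = pos, rule = 2)$y
    }
  }
  out
}

# --- empirical-Bayes variance moderation -----------------------------------

# Newton solve of trigamma(y) = x
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2)
      y <- y + dif
      if (abs(dif) < 1e-10 * y) break
    }
    y
  }, 1)
}

# Method-of-moments fit of a scaled F distribution to sample variances s2
# with df degrees of freedom; returns prior df d0 and prior variance s0^2.
fit_fdist <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0 = mean(s2[is.finite(s2)], na.rm = TRUE)))
  z <- log(s2[ok])
  dfo <- df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  raw_var <- sum((e - emean)^2) / (length(e) - 1)
  if (raw_var < 1e-15) {
    # all sample variances identical: the chi-square sampling noise the log-
    # scale bias correction assumes is absent, so the common value IS s0^2
    return(list(d0 = Inf, s0 = mean(s2[ok])))
  }
  evar <- raw_var - mean(trigamma(dfo / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(emean)
  }
  list(d0 = d0, s0 = s0)
}

#' Moderated two-group differential abundance fit
#'
#' Per protein, a two-group comparison on the pseudo-bulk cells with
#' empirical-Bayes variance moderation: the posterior variance is
#' `s2_tilde = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)` with the prior
#' `(d0, s0^2)` estimated from the distribution of log sample variances by
#' the method of moments. The moderated t is `log2fc / (s_tilde * sqrt(v_g))`
#' on `d0 + d_g` degrees of freedom, with a two-sided p-value. In the paired
#' design the comparison is blocked by participant (per-participant
#' differences); unpaired uses the pooled two-sample variance. Proteins need
#' complete observations in at least 2 cells per arm (unpaired) or 2
#' participants carrying both groups (paired). When fewer than 5 proteins
#' support prior estimation, ordinary t-statistics are used and a message is
#' emitted.
#'
#' @param pb a [pseudobulk_median()] result (normalise first if desired).
#' @param contrast character of length 2: groups `c(A, B)`; fold changes are
#'   `A - B` on the log2 scale.
#' @param paired block by participant?
#' @param alpha significance level applied to the composite pi-value.
#' @return A `diffabund` data frame: `protein`, `log2fc`, `t_mod`, `p_raw`,
#'   `xiao_pi`, `significant`, `n_A`, `n_B`; attributes `contrast`, `alpha`,
#'   `d0`, `s0`, `moderated`.
#' @export
fit_diffabund <- function(pb, contrast, paired = FALSE, alpha = 0.05) {
  if (!inherits(pb, "pseudobulk")) stop_invalid("`pb` must be a pseudobulk object")
  if (length(contrast) != 2L) stop_invalid("`contrast` must name two groups")
  gA <- contrast[1]; gB <- contrast[2]
  iA <- which(pb$cells$group == gA)
  iB <- which(pb$cells$group == gB)
  if (!length(iA) || !length(iB))
    stop_invalid("contrast groups not present in pseudobulk: %s vs %s", gA, gB)

  stats_one <- function(v) {
    if (paired) {
      pA <- pb$cells$participant[iA]; pB <- pb$cells$participant[iB]
      common <- intersect(pA, pB)
      a <- v[iA][match(common, pA)]
      b <- v[iB][match(common, pB)]
      ok <- !is.na(a) & !is.na(b)
      n <- sum(ok)
      if (n < 2) return(c(NA, NA, NA, n, n))
      d <- a[ok] - b[ok]
      c(mean(d), stats::var(d), n - 1, n, n)
    } else {
      a <- v[iA][!is.na(v[iA])]
      b <- v[iB][!is.na(v[iB])]
      nA <- length(a); nB <- length(b)
      if (nA < 2 || nB < 2) return(c(NA, NA, NA, nA, nB))
      s2 <- ((nA - 1) * stats::var(a) + (nB - 1) * stats::var(b)) / (nA + nB - 2)
      c(mean(a) - mean(b), s2, nA + nB - 2, nA, nB)
    }
  }
  st <- t(apply(pb$values, 1, stats_one))
  colnames(st) <- c("fc", "s2", "df", "nA", "nB")
  usable <- which(!is.na(st[, "fc"]))
  fc <- st[usable, "fc"]; s2 <- st[usable, "s2"]; df <- st[usable, "df"]
  vg <- if (paired) 1 / st[usable, "nA"]
        else 1 / st[usable, "nA"] + 1 / st[usable, "nB"]

  moderated <- length(usable) >= 5L
  if (moderated) {
    prior <- fit_fdist(s2, df)
    d0 <- prior$d0; s0 <- prior$s0
    if (!is.finite(s0) || is.na(d0)) moderated <- FALSE
  }
  if (moderated) {
    if (is.finite(d0)) {
      s2t <- (d0 * s0 + df * s2) / (d0 + df)
      dft <- d0 + df
    } else {
      s2t <- rep(s0, length(s2)); dft <- rep(Inf, length(s2))
    }
  } else {
    message("fewer than 5 usable proteins: falling back to ordinary t")
    d0 <- 0; s0 <- NA_real_
    s2t <- s2; dft <- df
  }
  tmod <- fc / sqrt(s2t * vg)
  p <- 2 * stats::pt(-abs(tmod), df = dft)
  p[s2t == 0 & fc == 0] <- 1   # 0/0: no evidence of change
  p[s2t == 0 & fc != 0] <- 0   # exact separation

  out <- data.frame(protein = rownames(pb$values)[usable],
                    log2fc = unname(fc), t_mod = unname(tmod),
                    p_raw = unname(p), stringsAsFactors = FALSE)
  out$xiao_pi <- xiao_pi(out$p_raw, out$log2fc)
  out$significant <- out$xiao_pi < alpha
  out$n_A <- unname(st[usable, "nA"])
  out$n_B <- unname(st[usable, "nB"])
  rownames(out) <- NULL
  structure(out, class = c("diffabund", "data.frame"),
            contrast = contrast, alpha = alpha, d0 = d0, s0 = s0,
            moderated = moderated)
}

#' @export
print.diffabund <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("<diffabund> %s vs %s: %d proteins tested, %d significant (pi < %s)\n",
              ct[1], ct[2], nrow(x), sum(x$significant), attr(x, "alpha")))
  cat(sprintf("prior df d0 = %.3g, prior variance s0^2 = %.3g\n",
              attr(x, "d0"), attr(x, "s0")))
  NextMethod()
}

#' Composite fold-change / p-value significance score (pi-value)
#'
#' `pi = p^|log2fc|`, equivalently `10^(-s)` with
#' `s = |log2fc| * (-log10 p)`: small only when the change is both large and
#' statistically supported. A p-value of exactly zero is clipped to the
#' smallest positive double with a warning.
#'
#' @param p_raw unadjusted p-value(s) in `(0, 1]`.
#' @param log2fc finite log2 fold change(s).
#' @return pi-value(s) in `[0, 1]` for `p` in `(0, 1]`.
#' @export
xiao_pi <- function(p_raw, log2fc) {
  if (any(!is.finite(log2fc)))
    stop_invalid("log2fc must be finite")
  if (any(is.na(p_raw)) || any(p_raw < 0) || any(p_raw > 1))
    stop_invalid("p_raw must lie in [0, 1]")
  if (any(p_raw == 0)) {
    warning("p = 0 clipped to smallest positive double", call. = FALSE)
    p_raw[p_raw == 0] <- .Machine$double.xmin
  }
  p_raw^abs(log2fc)
}

#' Select significant proteins by composite score
#'
#' @param results a `diffabund` data frame.
#' @param alpha strict threshold: kept when `xiao_pi < alpha`.
#' @return The significant subset, with attributes `n_up` / `n_down`
#'   (direction counts by sign of `log2fc`).
#' @export
significant_hits <- function(results, alpha = 0.05) {
  keep <- results[results$xiao_pi < alpha, , drop = FALSE]
  structure(keep, n_up = sum(keep$log2fc > 0), n_down = sum(keep$log2fc < 0))
}

#' Differential abundance between high- and low-SRX fibre clusters
#'
#' Classifies fibres by SRX percentage ([srx_class()]), aggregates to
#' pseudo-bulk per (participant, cluster), restricts to participants that
#' contain both clusters, quantile-normalises, and runs the paired moderated
#' fit of high versus low.
#'
#' @param pm a log2-scale `protein_matrix`.
#' @param srx named numeric vector of SRX percentages by fibre id (e.g. the
#'   `srx_pct` column of [fit_decay_traces()]).
#' @param low_cut,high_cut cluster boundaries (percent).
#' @param alpha composite significance level.
#' @return A `diffabund` result (high vs low) with attribute
#'   `participants_used`.
#' @export
srx_cluster_contrast <- function(pm, srx, low_cut = 35, high_cut = 65,
                                 alpha = 0.05) {
  srx <- srx[names(srx) %in% colnames(pm$values)]
  cl <- srx_class(srx, low_cut, high_cut)
  grouping <- stats::setNames(ifelse(cl == "mid", NA, cl), names(srx))
  ann <- pm$annotations
  part <- ann$participant[match(names(grouping), ann$fibre_id)]
  has_both <- vapply(unique(part), function(p) {
    g <- grouping[part == p]
    all(c("low", "high") %in% g)
  }, TRUE)
  qualifying <- unique(part)[has_both]
  excluded <- setdiff(unique(part), qualifying)
  if (length(excluded))
    message("participants without both SRX clusters excluded: ",
            paste(excluded, collapse = ", "))
  if (length(qualifying) < 2L)
    stop_invalid("insufficient data: fewer than 2 participants contain both SRX clusters")
  grouping[!part %in% qualifying] <- NA
  pb <- quantile_normalise(pseudobulk_median(pm, grouping))
  out <- fit_diffabund(pb, c("high", "low"), paired = TRUE, alpha = alpha)
  attr(out, "participants_used") <- qualifying
  out
}

#' Overlap and direction concordance of two significant sets
#'
#' @param setA,setB `diffabund` results (already scored).
#' @param alpha significance level applied to both.
#' @return List with `common` (proteins significant in both),
#'   `concordant_count` (same sign of log2fc), and `discordant` (protein ids
#'   changing in opposite directions).
#' @export
overlap_direction <- function(setA, setB, alpha = 0.05) {
  a <- significant_hits(setA, alpha)
  b <- significant_hits(setB, alpha)
  common <- intersect(a$protein, b$protein)
  sa <- sign(a$log2fc[match(common, a$protein)])
  sb <- sign(b$log2fc[match(common, b$protein)])
  list(common = common,
       concordant_count = sum(sa == sb),
       discordant = common[sa != sb])
}

#' Pseudo-bulk contrast from fibre-level grouping in one call
#'
#' Convenience wrapper: pseudo-bulk medians, quantile normalisation,
#' moderated fit, composite scoring.
#'
#' @param pm log2-scale `protein_matrix`.
#' @param grouping named fibre -> group vector (NA to drop a fibre).
#' @param contrast `c(A, B)` group labels.
#' @param paired block by participant?
#' @param alpha composite significance level.
#' @return A `diffabund` result.
#' @export
diffabund_contrast <- function(pm, grouping, contrast, paired = FALSE,
                               alpha = 0.05) {
  pb <- quantile_normalise(pseudobulk_median(pm, grouping))
  fit_diffabund(pb, contrast, paired = paired, alpha = alpha)
}
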