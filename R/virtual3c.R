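# Virtual 3C: per-anchor contact-decay profiles sliced out of a binned
# contact map, filtered by TAD containment, classified by epigenetic
# domain, batch-fitted with the unconstrained model, and summarized per
# chromosome x domain.

#' Build virtual-3C profiles from a binned contact map
#'
#' Slides a 25-kb anchor window (5 bins of 5 kb) along the chromosome in
#' 5-kb steps and, for each anchor, extracts a contact-decay profile over
#' a 400-kb downstream window: the profile value at genomic separation
#' `d` is the mean of the `anchor_width/bin` contact values observed at
#' exactly that separation from each anchor bin (anchor bin `a+k` paired
#' with bin `a+k+d/bin`). Averaging at constant separation keeps the
#' profile an unbiased estimate of the per-bin-pair decay curve. Only
#' anchors whose full span `[a, a + span)` lies on the chromosome are
#' produced, so on a gap-free chromosome the number of profiles is
#' `n_bins - span/bin + 1`.
#'
#' @param map A [contact_map()].
#' @param anchor_width_kb Anchor window width, kb (multiple of the bin
#'   size).
#' @param span_kb Downstream window, kb (multiple of the bin size);
#'   profile separations run from one bin to `span_kb - anchor_width_kb`.
#' @return A `virtual_profiles` object: a `data.frame` with columns
#'   `anchor_bin` (0-based anchor start bin), `separation_kb`,
#'   `frequency`, plus map metadata in attributes.
#' @export
build_virtual_profiles <- function(map, anchor_width_kb = 25,
                                   span_kb = 400) {
  stopifnot(inherits(map, "binned_contact_map"))
  bs <- map$bin_size_kb
  if (anchor_width_kb %% bs != 0 || span_kb %% bs != 0) {
    stop("`anchor_width_kb` and `span_kb` must be multiples of the bin size")
  }
  aw <- as.integer(anchor_width_kb / bs)
  sp <- as.integer(span_kb / bs)
  stopifnot(aw >= 1, sp > aw)
  n <- map$n_bins
  n_anchors <- max(0L, n - sp + 1L)
  sep_bins <- seq_len(sp - aw)
  if (n_anchors == 0L) {
    out <- data.frame(anchor_bin = integer(0), separation_kb = numeric(0),
                      frequency = numeric(0))
  } else {
    vals <- matrix(NA_real_, nrow = n_anchors, ncol = length(sep_bins))
    for (c_idx in seq_along(sep_bins)) {
      db <- sep_bins[c_idx]
      i <- seq_len(n - db)
      diag_vals <- map$mat[cbind(i, i + db)]
      cs <- c(0, cumsum(diag_vals))
      a <- seq_len(n_anchors)
      vals[, c_idx] <- (cs[a + aw] - cs[a]) / aw
    }
    out <- data.frame(
      anchor_bin = rep(0:(n_anchors - 1L), times = length(sep_bins)),
      separation_kb = rep(sep_bins * bs, each = n_anchors),
      frequency = as.vector(vals)
    )
    out <- out[order(out$anchor_bin, out$separation_kb), ]
    rownames(out) <- NULL
  }
  structure(out,
    chrom = map$chrom, bin_size_kb = bs, n_bins = n,
    anchor_width_kb = anchor_width_kb, span_kb = span_kb,
    class = c("virtual_profiles", "data.frame")
  )
}

#' @export
print.virtual_profiles <- function(x, ...) {
  cat(sprintf(
    "<virtual_profiles> %s: %d anchors x up to %d separations (anchor %g kb, span %g kb)\n",
    attr(x, "chrom"), length(unique(x$anchor_bin)),
    length(unique(x$separation_kb)), attr(x, "anchor_width_kb"),
    attr(x, "span_kb")
  ))
  invisible(x)
}

.vp_subset <- function(vp, keep_anchor) {
  at <- attributes(vp)
  out <- as.data.frame(vp)[vp$anchor_bin %in% keep_anchor, , drop = FALSE]
  rownames(out) <- NULL
  for (a in setdiff(names(at), c("names", "row.names", "class"))) {
    attr(out, a) <- at[[a]]
  }
  class(out) <- c("virtual_profiles", "data.frame")
  out
}

.anchor_granges <- function(vp, width_kb) {
  bs <- attr(vp, "bin_size_kb")
  anchors <- sort(unique(vp$anchor_bin))
  start_bp0 <- anchors * bs * 1000
  list(
    anchors = anchors,
    gr = GenomicRanges::GRanges(
      seqnames = attr(vp, "chrom"),
      ranges = IRanges::IRanges(start = start_bp0 + 1,
                                end = start_bp0 + width_kb * 1000)
    )
  )
}

#' Keep profiles confined to a single TAD
#'
#' Retains anchors whose window plus `min_span_kb` of downstream sequence
#' lies entirely within one annotated TAD, so that the retained decay
#' profiles never cross a TAD border over the span that will be analysed.
#' When the profiles are later fitted over their first `fit_span_kb`,
#' pass `min_span_kb = fit_span_kb` for strict containment of every
#' fitted bin pair.
#'
#' @param vp A [build_virtual_profiles()] result.
#' @param tads A `GRanges` of non-overlapping TAD intervals on the same
#'   chromosome (e.g. from [simulate_genome()] or
#'   [read_bed_annotation()]).
#' @param min_span_kb Required in-TAD span downstream of the anchor
#'   window, kb.
#' @return The filtered `virtual_profiles`.
#' @export
filter_within_tad <- function(vp, tads, min_span_kb = 65) {
  stopifnot(inherits(vp, "virtual_profiles"),
            methods::is(tads, "GRanges"), min_span_kb >= 0)
  req <- .anchor_granges(vp, attr(vp, "anchor_width_kb") + min_span_kb)
  hits <- GenomicRanges::findOverlaps(req$gr, tads, type = "within")
  keep <- req$anchors[unique(S4Vectors::queryHits(hits))]
  .vp_subset(vp, keep)
}

#' Classify profiles by epigenetic domain
#'
#' Labels every anchor by the epigenetic class (D1-D4) with the majority
#' base-pair overlap of its anchor window; exact ties and windows with no
#' overlap are left unassigned (`NA`) and drop out of the per-domain
#' statistics.
#'
#' @param vp A [build_virtual_profiles()] result.
#' @param domains A `GRanges` of non-overlapping labelled intervals
#'   (metadata column `name` holding D1-D4).
#' @return `vp` with an added per-row `domain` column.
#' @export
classify_profiles <- function(vp, domains) {
  stopifnot(inherits(vp, "virtual_profiles"), methods::is(domains, "GRanges"))
  win <- .anchor_granges(vp, attr(vp, "anchor_width_kb"))
  hits <- GenomicRanges::findOverlaps(win$gr, domains)
  label <- rep(NA_character_, length(win$anchors))
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(
      win$gr[S4Vectors::queryHits(hits)],
      domains[S4Vectors::subjectHits(hits)]
    )
    df <- data.frame(
      q = S4Vectors::queryHits(hits),
      lab = S4Vectors::mcols(domains)$name[S4Vectors::subjectHits(hits)],
      w = GenomicRanges::width(ov)
    )
    agg <- stats::aggregate(w ~ q + lab, data = df, FUN = sum)
    for (qi in unique(agg$q)) {
      sub <- agg[agg$q == qi, ]
      top <- sub$w == max(sub$w)
      if (sum(top) == 1L) label[qi] <- sub$lab[top]
    }
  }
  out <- as.data.frame(vp)
  out$domain <- label[match(out$anchor_bin, win$anchors)]
  at <- attributes(vp)
  for (a in setdiff(names(at), c("names", "row.names", "class"))) {
    attr(out, a) <- at[[a]]
  }
  class(out) <- c("virtual_profiles", "data.frame")
  out
}

#' Batch-fit the unconstrained model to virtual-3C profiles
#'
#' Fits the unconstrained contact-frequency model with `K`, `L` and `S`
#' all free (uniform weights) to each profile's points with separations
#' from `min_sep_kb` up to `fit_span_kb` (default: all 14 five-kb bins of
#' the first 70 kb; every profile point is a constant-separation mean of
#' genuine bin pairs, so small separations carry no self-contact and are
#' the ones that identify `S`). Because `K` and `L` enter the model
#' only through `K * (L*S)^-3`, only `S` and the overall amplitude are
#' statistically identifiable; the fitted `L` stays close to its starting
#' value and its standard error is reported `NA` (see the methods
#' vignette). Profiles with fewer than 4 usable points, or that are
#' all-zero/degenerate, are flagged `converged = FALSE` with `NA`
#' parameters.
#'
#' @param vp A (possibly filtered/classified) `virtual_profiles` object.
#' @param fit_span_kb Fit the first `fit_span_kb` of each profile
#'   (default 70 kb, i.e. 14 bins of 5 kb).
#' @param min_sep_kb Smallest separation included in the fit; defaults to
#'   one bin.
#' @param start Named starting values `c(L = , S = )` for the free fit.
#' @param control A [fit_control()] (the Kuhn-segment multi-start uses
#'   `start * c(0.5, 1, 2)`).
#' @return A `virtual_fit_table`: a `data.frame` with one row per anchor
#'   (`anchor_bin`, `domain` if classified, `K`, `L`, `S`, standard
#'   errors, `r_squared`, `ssr`, `n_obs`, `converged`), chromosome in
#'   attribute `chrom`.
#' @export
fit_virtual_profiles <- function(vp, fit_span_kb = 70,
                                 min_sep_kb = attr(vp, "bin_size_kb"),
                                 start = c(L = 10.6, S = 5),
                                 control = fit_control()) {
  stopifnot(inherits(vp, "virtual_profiles"),
            all(c("L", "S") %in% names(start)))
  aw_kb <- attr(vp, "anchor_width_kb")
  anchors <- sort(unique(vp$anchor_bin))
  has_domain <- "domain" %in% names(vp)
  rows <- vector("list", length(anchors))
  for (idx in seq_along(anchors)) {
    a <- anchors[idx]
    sub <- vp[vp$anchor_bin == a & vp$separation_kb >= min_sep_kb &
                vp$separation_kb <= fit_span_kb, , drop = FALSE]
    dom <- if (has_domain) sub$domain[1] else NA_character_
    base <- data.frame(
      anchor_bin = a, domain = dom,
      K = NA_real_, L = NA_real_, S = NA_real_,
      se_K = NA_real_, se_L = NA_real_, se_S = NA_real_,
      r_squared = NA_real_, ssr = NA_real_,
      n_obs = nrow(sub), converged = FALSE,
      stringsAsFactors = FALSE
    )
    usable <- nrow(sub) >= 4L && any(sub$frequency > 0) &&
      stats::var(sub$frequency) > 0
    if (usable) {
      pr <- contact_profile(sub$separation_kb, sub$frequency)
      ctl <- control
      ctl$start_L <- start[["L"]]
      ctl$start_S_unconstrained <- start[["S"]] * c(0.5, 1, 2)
      fit <- fit_unconstrained(pr, L = "free", weights = "uniform",
                               control = ctl)
      base$K <- fit$params[["K"]]
      base$L <- fit$params[["L"]]
      base$S <- fit$params[["S"]]
      base$se_K <- fit$stderr[["K"]]
      base$se_L <- fit$stderr[["L"]]
      base$se_S <- fit$stderr[["S"]]
      base$r_squared <- fit$r_squared
      base$ssr <- fit$ssr
      base$converged <- fit$converged
    }
    rows[[idx]] <- base
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
    chrom = attr(vp, "chrom"), fit_span_kb = fit_span_kb,
    anchor_width_kb = aw_kb,
    class = c("virtual_fit_table", "data.frame")
  )
}

#' Filter virtual-3C fits by quality
#'
#' Retains converged fits whose coefficient of determination lies
#' strictly in `(0, 1)` and reports the fraction of the retained fits
#' with `R^2 > 0.5` (the summary statistic used to judge how widely the
#' unconstrained model applies).
#'
#' @param fits A [fit_virtual_profiles()] table.
#' @return A list with `retained` (the filtered table) and
#'   `fraction_r2_above_half` (`NA` with a warning when nothing is
#'   retained).
#' @export
filter_fit_quality <- function(fits) {
  stopifnot(inherits(fits, "virtual_fit_table"))
  keep <- fits$converged & is.finite(fits$r_squared) &
    fits$r_squared > 0 & fits$r_squared < 1
  retained <- fits[keep, , drop = FALSE]
  rownames(retained) <- NULL
  at <- attributes(fits)
  for (a in setdiff(names(at), c("names", "row.names", "class"))) {
    attr(retained, a) <- at[[a]]
  }
  class(retained) <- class(fits)
  frac <- if (nrow(retained) == 0L) {
    warning("no fits retained; fraction is undefined")
    NA_real_
  } else {
    mean(retained$r_squared > 0.5)
  }
  list(retained = retained, fraction_r2_above_half = frac)
}

#' Per-domain medians and pairwise rank tests of fitted parameters
#'
#' Summarizes a virtual-3C fit table per epigenetic domain: the median of
#' each fitted parameter (`K`, `L`, `S`), and for every domain pair and
#' parameter an unpaired two-sided Wilcoxon rank-sum (Mann-Whitney)
#' p-value. Pairs where either group has fewer than 2 fits are skipped
#' (`NA` p-value); medians are always reported. Unassigned (`NA` domain)
#' fits are dropped.
#'
#' @param fits A [fit_virtual_profiles()] (typically quality-filtered)
#'   table with a `domain` column.
#' @param params Parameters to summarize.
#' @return A list with `medians` (`data.frame`: `chrom`, `domain`, `n`,
#'   `median_K`, `median_L`, `median_S`) and `tests` (`data.frame`:
#'   `chrom`, `parameter`, `domain_a`, `domain_b`, `n_a`, `n_b`,
#'   `p_value`).
#' @export
domain_parameter_summary <- function(fits, params = c("K", "L", "S")) {
  stopifnot(inherits(fits, "virtual_fit_table"),
            "domain" %in% names(fits))
  chrom <- attr(fits, "chrom")
  fits <- fits[!is.na(fits$domain), , drop = FALSE]
  doms <- sort(unique(fits$domain))
  if (length(doms) == 0L) stop("no domain-assigned fits to summarize")
  medians <- do.call(rbind, lapply(doms, function(d) {
    sub <- fits[fits$domain == d, , drop = FALSE]
    row <- data.frame(chrom = chrom, domain = d, n = nrow(sub))
    for (p in params) row[[paste0("median_", p)]] <- stats::median(sub[[p]])
    row
  }))
  tests <- NULL
  if (length(doms) >= 2L) {
    pairs <- utils::combn(doms, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      da <- pairs[1, i]; db <- pairs[2, i]
      xa <- fits[fits$domain == da, , drop = FALSE]
      xb <- fits[fits$domain == db, , drop = FALSE]
      do.call(rbind, lapply(params, function(p) {
        ok <- nrow(xa) >= 2L && nrow(xb) >= 2L
        data.frame(
          chrom = chrom, parameter = p, domain_a = da, domain_b = db,
          n_a = nrow(xa), n_b = nrow(xb),
          p_value = if (ok) {
            mann_whitney_u(xa[[p]], xb[[p]])$p_value
          } else NA_real_,
          stringsAsFactors = FALSE
        )
      }))
    }))
    rownames(tests) <- NULL
  }
  rownames(medians) <- NULL
  list(medians = medians, tests = tests)
}
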