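#' Positional residue counts across aligned cleavage windows
#'
#' Tallies, for each subsite P6-P6' and each of the 20 standard residues,
#' how many windows carry that residue there. `X`-masked observations are
#' tallied separately per position, so at every position
#' `sum(counts) + x_count == n_sites`.
#'
#' @param windows A `window_set` (from [reconstruct_all()] or
#'   [read_windows_tsv()]), or a character vector of 12-character
#'   windows. All windows must belong to a single protease.
#' @param protease Optional label; inferred from `windows` when omitted.
#' @return An object of class `positional_counts`: list with `protease`,
#'   `n_sites`, `counts` (20 x 12 integer matrix, residues x subsites)
#'   and `x_counts` (length-12 integer vector).
#' @export
#' @examples
#' m <- count_matrix(c("MAVIGRKFGDPL", "MAVIGRKFGDPL"))
#' m$counts["R", "P1"]
count_matrix <- function(windows, protease = NULL) {
  if (is.data.frame(windows)) {
    prot <- unique(windows$protease)
    if (length(prot) > 1L) {
      stop("windows mix proteases (", paste(prot, collapse = ", "),
           "); profile one protease at a time", call. = FALSE)
    }
    if (is.null(protease)) protease <- if (length(prot)) prot else "protease"
    win <- windows$window
  } else {
    win <- as.character(windows)
    if (is.null(protease)) protease <- "protease"
  }
  if (length(win) && any(nchar(win) != 12L)) {
    stop("all windows must be exactly 12 residues (P6-P6')", call. = FALSE)
  }
  counts <- matrix(0L, nrow = 20L, ncol = 12L,
                   dimnames = list(AA20, SUBSITES))
  x_counts <- stats::setNames(integer(12L), SUBSITES)
  if (length(win)) {
    mat <- do.call(rbind, strsplit(win, "", fixed = TRUE))
    bad <- setdiff(unique(as.vector(mat)), AA21)
    if (length(bad)) stop("illegal residue(s) in windows: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (j in seq_len(12L)) {
      tab <- table(factor(mat[, j], levels = AA21))
      counts[, j] <- as.integer(tab[AA20])
      x_counts[j] <- as.integer(tab["X"])
    }
  }
  structure(
    list(protease = protease, n_sites = length(win),
         counts = counts, x_counts = x_counts),
    class = "positional_counts"
  )
}

#' @export
print.positional_counts <- function(x, ...) {
  cat(sprintf("positional counts for '%s': %d site(s)\n", x$protease, x$n_sites))
  top <- apply(x$counts, 2L, function(col) AA20[which.max(col)])
  cat("top residue per subsite:\n")
  print(top)
  invisible(x)
}

#' Per-cell occurrence percentages (heat-map values)
#'
#' Converts positional counts to the percentage display used in
#' specificity heat maps: at each subsite the denominator is the number
#' of windows with an unmasked residue there (`n_sites - x_count`), so a
#' residue seen in every informative window reads 100%. Subsites where
#' every window is masked yield `NA` throughout.
#'
#' @param matrix A `positional_counts` object.
#' @return 20 x 12 numeric matrix of percentages.
#' @export
occurrence_percent <- function(matrix) {
  stopifnot(inherits(matrix, "positional_counts"))
  if (matrix$n_sites < 1L) stop("no sites tallied", call. = FALSE)
  denom <- matrix$n_sites - matrix$x_counts
  pct <- sweep(matrix$counts, 2L, denom, "/") * 100
  pct[, denom == 0L] <- NA_real_
  pct
}

#' Background-normalised positional enrichment with significance
#'
#' The iceLogo-style readout: for every (subsite, residue) cell, the
#' observed fraction among unmasked windows is compared with the
#' residue's natural abundance in the background proteome. The fold
#' change is `observed / background`; significance comes, per cell, from
#' a two-sided exact binomial test of the observed count against the
#' background probability with `n` = unmasked windows at that subsite
#' (a z-test on proportions is available via `test = "ztest"`). Calls:
#'
#' * `"over"` / `"under"`: `p < alpha` with fold above/below 1;
#' * `"absent"`: the residue was never observed although its expected
#'   count is at least `absent_min_expected` (absence is only meaningful
#'   when it is surprising);
#' * `"ns"`: everything else.
#'
#' No multiple-testing correction is applied: `alpha` is a per-cell
#' threshold, matching how positional enrichment logos are conventionally
#' thresholded.
#'
#' @param matrix A `positional_counts` object.
#' @param background An `aa_background` vector
#'   (see [background_composition()]).
#' @param alpha Per-cell significance level (default 0.01).
#' @param test `"binomial"` (exact, default) or `"ztest"` (normal
#'   approximation with continuity correction).
#' @param absent_min_expected Minimum expected count for an `"absent"`
#'   call (default 5).
#' @return `data.frame` of class `enrichment_profile` with one row per
#'   (position, residue): `position`, `residue`, `count`, `n_eff`,
#'   `observed`, `background`, `fold`, `p_value`, `call`, plus
#'   attributes `protease`, `n_sites` and `alpha`. Cells with zero
#'   background and a nonzero count carry `fold = Inf`.
#' @export
enrichment_profile <- function(matrix, background, alpha = 0.01,
                               test = c("binomial", "ztest"),
                               absent_min_expected = 5) {
  stopifnot(inherits(matrix, "positional_counts"),
            inherits(background, "aa_background"),
            matrix$n_sites >= 1L, alpha > 0, alpha < 1)
  test <- match.arg(test)
  denom <- matrix$n_sites - matrix$x_counts
  rows <- vector("list", 12L * 20L)
  k <- 0L
  for (j in seq_len(12L)) {
    n <- denom[j]
    for (a in AA20) {
      k <- k + 1L
      cnt <- matrix$counts[a, j]
      bg <- unname(background[a])
      obs <- if (n > 0L) cnt / n else NA_real_
      fold <- if (n == 0L) NA_real_
              else if (bg > 0) obs / bg
              else if (cnt > 0L) Inf else NA_real_
      p <- if (n == 0L || bg <= 0 || bg >= 1) NA_real_
           else if (test == "binomial") {
             stats::binom.test(cnt, n, p = bg)$p.value
           } else {
             prop_ztest(cnt, n, bg)
           }
      call <- "ns"
      if (!is.na(p) && p < alpha && !is.na(fold)) {
        if (fold > 1) call <- "over" else if (fold < 1) call <- "under"
      }
      if (n > 0L && cnt == 0L && n * bg >= absent_min_expected) call <- "absent"
      rows[[k]] <- list(position = SUBSITES[j], residue = a, count = cnt,
                        n_eff = n, observed = obs, background = bg,
                        fold = fold, p_value = p, call = call)
    }
  }
  out <- do.call(rbind.data.frame, rows)
  out$position <- factor(out$position, levels = SUBSITES)
  attr(out, "protease") <- matrix$protease
  attr(out, "n_sites") <- matrix$n_sites
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

# two-sided one-sample proportion z-test with continuity correction
prop_ztest <- function(count, n, p0) {
  se <- sqrt(p0 * (1 - p0) / n)
  cc <- min(abs(count / n - p0), 0.5 / n)
  z <- (abs(count / n - p0) - cc) / se
  2 * stats::pnorm(-z)
}

#' Subsite position weight matrix from an enrichment profile
#'
#' Pseudocount-smoothed log2 odds of observing each residue at each
#' subsite relative to its natural abundance:
#' `log2( (count + c) / (n + 20 c) / background )` with pseudocount `c`.
#' Subsites with no informative windows (`n_eff = 0`) score zero
#' throughout, so they neither reward nor penalise candidates.
#'
#' @param profile An `enrichment_profile`.
#' @param pseudocount Smoothing constant `c` (default 0.5, Jeffreys-style;
#'   keeps log-odds finite at zero counts).
#' @return 20 x 12 numeric matrix of class `subsite_pwm`.
#' @export
pwm_from_profile <- function(profile, pseudocount = 0.5) {
  stopifnot(inherits(profile, "enrichment_profile"), pseudocount > 0)
  pwm <- matrix(0, nrow = 20L, ncol = 12L, dimnames = list(AA20, SUBSITES))
  for (i in seq_len(nrow(profile))) {
    pos <- as.character(profile$position[i])
    a <- profile$residue[i]
    n <- profile$n_eff[i]
    bg <- profile$background[i]
    if (n > 0L && bg > 0) {
      smoothed <- (profile$count[i] + pseudocount) / (n + 20 * pseudocount)
      pwm[a, pos] <- log2(smoothed / bg)
    }
  }
  class(pwm) <- c("subsite_pwm", class(pwm))
  pwm
}

#' Score a candidate P6-P6' window against a subsite PWM
#'
#' Sums the PWM entries at every non-X position of a 12-character window;
#' `X` contributes zero, so partially known windows (e.g. the P4-P4'
#' stretches tabulated for natural substrates) can be scored by X-padding
#' to 12 characters. Higher scores indicate windows more consistent with
#' the profiled specificity.
#'
#' @param pwm A `subsite_pwm`.
#' @param window A 12-character string over the 21-letter alphabet.
#' @return Numeric score.
#' @export
#' @examples
#' # score the CDCP1 cleavage window (P4-P4' known, X-padded to P6-P6')
#' # against a profile; see vignette for a full worked example
score_window <- function(pwm, window) {
  stopifnot(inherits(pwm, "subsite_pwm"))
  check_sequence(window, what = "window")
  if (nchar(window) != 12L) {
    stop("window must be exactly 12 residues (use X padding)", call. = FALSE)
  }
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  s <- 0
  for (j in seq_len(12L)) {
    if (chars[j] != "X") s <- s + pwm[chars[j], SUBSITES[j]]
  }
  s
}

#' Write a residue-by-subsite table as TSV
#'
#' Works for [occurrence_percent()] matrices and `subsite_pwm` objects:
#' rows are residues, columns are subsites, with a leading `residue`
#' column.
#'
#' @param x A 20 x 12 matrix with residue rownames.
#' @param path File path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(residue = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
write_profile_tsv <- function(x, path) {
  stopifnot(inherits(x, "enrichment_profile"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarise an enrichment profile
#'
#' @param object An `enrichment_profile`.
#' @param top_n Residues listed per subsite (default 3).
#' @param ... Unused.
#' @return List with `protease`, `n_sites`, `alpha`, `top_residues`
#'   (highest observed fraction per subsite) and `significant` (rows
#'   called over/under/absent).
#' @export
summary.enrichment_profile <- function(object, top_n = 3L, ...) {
  top <- lapply(split(object, object$position), function(d) {
    d <- d[order(-d$observed), ]
    utils::head(d$residue, top_n)
  })
  sig <- object[object$call != "ns", c("position", "residue", "fold",
                                       "p_value", "call")]
  list(protease = attr(object, "protease"),
       n_sites = attr(object, "n_sites"),
       alpha = attr(object, "alpha"),
       top_residues = top,
       significant = sig)
}

#' Plot a specificity heat map
#'
#' Renders [occurrence_percent()] values as a residue-by-subsite tile
#' plot (requires ggplot2).
#'
#' @param matrix A `positional_counts` object.
#' @param title Plot title; defaults to the protease label and site count.
#' @return A ggplot object.
#' @export
plot_specificity_heatmap <- function(matrix, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  pct <- occurrence_percent(matrix)
  df <- data.frame(
    residue = factor(rep(rownames(pct), times = ncol(pct)), levels = rev(AA20)),
    position = factor(rep(colnames(pct), each = nrow(pct)), levels = SUBSITES),
    percent = as.vector(pct)
  )
  if (is.null(title)) {
    title <- sprintf("%s (n = %d cleaved peptides)", matrix$protease,
                     matrix$n_sites)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = position, y = residue, fill = percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 na.value = "grey80") +
    ggplot2::labs(title = title, x = "subsite", y = "residue",
                  fill = "% occurrence") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment logo
#'
#' Bar rendering of the iceLogo semantics: significantly over-represented
#' residues plot upwards with height proportional to fold enrichment,
#' under-represented residues plot downwards, absent residues are marked
#' at the bottom (requires ggplot2).
#'
#' @param profile An `enrichment_profile`.
#' @return A ggplot object.
#' @export
plot_enrichment_logo <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  sig <- profile[profile$call != "ns", , drop = FALSE]
  sig$height <- ifelse(sig$call == "over", sig$fold,
                       ifelse(sig$call == "under", -1 / pmax(sig$fold, 1e-6), -1))
  ggplot2::ggplot(sig, ggplot2::aes(x = position, y = height, label = residue,
                                    colour = call)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_text(position = ggplot2::position_stack(vjust = 0.5),
                       fontface = "bold") +
    ggplot2::scale_colour_manual(values = c(over = "black", under = "steelblue",
                                            absent = "deeppink")) +
    ggplot2::labs(x = "subsite", y = "fold enrichment (signed)",
                  title = sprintf("%s (n = %d)", attr(profile, "protease"),
                                  attr(profile, "n_sites"))) +
    ggplot2::theme_minimal()
}
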