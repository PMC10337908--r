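#' Assign nuclei to equal-length gonad zones
#'
#' The axis `[0, gonad_length]` is cut into `n_zones` equal intervals,
#' half-open on the right except the last, which is closed at the proximal
#' end: zone `i` covers `[(i-1) L/n, i L/n)` and position `L` falls in zone
#' `n`. Zone 1 is the most distal.
#'
#' @param layout A `gonad_layout` data frame (column `position`) or a
#'   numeric vector of positions.
#' @param n_zones Number of zones (>= 1).
#' @param gonad_length Axis length; taken from the layout attribute when
#'   available.
#' @return Integer zone per nucleus (1-based, distal to proximal).
#' @export
partition_zones <- function(layout, n_zones, gonad_length = NULL) {
  pos <- if (is.data.frame(layout)) layout$position else layout
  if (is.null(gonad_length)) gonad_length <- attr(layout, "gonad_length")
  if (is.null(gonad_length)) stop("gonad_length required")
  if (n_zones < 1 || gonad_length <= 0) stop("need n_zones >= 1 and gonad_length > 0")
  if (any(pos < 0 | pos > gonad_length)) {
    stop("positions must lie within [0, gonad_length]")
  }
  z <- floor(pos / gonad_length * n_zones) + 1L
  z[pos == gonad_length] <- as.integer(n_zones)
  as.integer(z)
}

#' Score X-chromosome pairing from HIM-8 focus counts
#'
#' A nucleus is paired when it shows at most `max_foci_paired` HIM-8 foci
#' (one focus = paired homologs, two = unpaired). Counts of zero satisfy
#' the threshold but are flagged for review (likely a detection failure),
#' reported via a message.
#'
#' @param focus_counts Integer focus counts per nucleus (>= 0).
#' @param max_foci_paired Maximum focus count still scored as paired.
#' @return Logical vector; attribute `review` marks zero-count nuclei.
#' @export
score_pairing <- function(focus_counts, max_foci_paired = 1) {
  if (any(focus_counts < 0)) stop("focus counts must be >= 0")
  paired <- focus_counts <= max_foci_paired
  review <- focus_counts == 0
  if (any(review)) {
    message(sum(review), " nucleus/nuclei with 0 HIM-8 foci scored as paired",
            " but flagged for review")
  }
  attr(paired, "review") <- review
  paired
}

#' Score complete synapsis from SYP-1/HTP-3 colocalization
#'
#' @param coloc_fraction Colocalization fraction per nucleus, in [0, 1].
#' @param threshold Minimum fraction counted as complete synapsis
#'   (default 0.95).
#' @return Logical vector.
#' @export
score_synapsis <- function(coloc_fraction, threshold = 0.95) {
  if (any(coloc_fraction < 0 | coloc_fraction > 1)) {
    stop("colocalization fractions must lie in [0, 1]")
  }
  coloc_fraction >= threshold
}

#' Per-zone fractions of nuclei satisfying a predicate
#'
#' Nuclei are assigned to equal-length zones and, per zone, the pooled
#' fraction satisfying the predicate is computed together with the
#' unweighted mean and sample SD of the per-animal fractions. Empty zones
#' are reported with `NA` fractions (missing, not zero).
#'
#' @param layout Data frame with columns `position`, `animal_id` and the
#'   predicate inputs; attribute `gonad_length` or argument required.
#' @param predicate Column name of a logical column (e.g. `"collapsed"`) or
#'   a function of the layout returning a logical per nucleus.
#' @param n_zones Number of zones.
#' @param gonad_length Axis length.
#' @return Data frame of class `zone_summary`: `zone`, `n`, `n_true`,
#'   `fraction`, `animal_mean`, `animal_sd`, `n_animals`.
#' @export
zone_fractions <- function(layout, predicate, n_zones, gonad_length = NULL) {
  if (is.null(gonad_length)) gonad_length <- attr(layout, "gonad_length")
  flag <- if (is.function(predicate)) predicate(layout) else layout[[predicate]]
  if (is.null(flag)) stop("predicate column '", predicate, "' not found")
  flag <- as.logical(flag)
  zone <- partition_zones(layout, n_zones, gonad_length)
  animal <- if (!is.null(layout$animal_id)) layout$animal_id else rep(1L, nrow(layout))
  if (length(unique(animal)) < 1) stop("need at least one animal")

  out <- do.call(rbind, lapply(seq_len(n_zones), function(z) {
    sel <- zone == z
    n <- sum(sel)
    if (n == 0) {
      return(data.frame(zone = z, n = 0L, n_true = 0L, fraction = NA_real_,
                        animal_mean = NA_real_, animal_sd = NA_real_,
                        n_animals = 0L))
    }
    per_animal <- tapply(flag[sel], animal[sel], mean)
    data.frame(zone = z, n = n, n_true = sum(flag[sel]),
               fraction = mean(flag[sel]),
               animal_mean = mean(per_animal),
               animal_sd = if (length(per_animal) > 1) sd(per_animal) else NA_real_,
               n_animals = length(per_animal))
  }))
  attr(out, "predicate") <- if (is.function(predicate)) "function" else predicate
  class(out) <- c("zone_summary", "data.frame")
  out
}

#' Compare per-zone proportions between two conditions
#'
#' Per zone, a two-sample proportion test on the 2x2 counts (chi-square
#' with continuity correction; Fisher's exact test when any expected count
#' falls below 5 or a margin is zero, noted in the `method` column), then
#' Benjamini-Hochberg adjustment across zones.
#'
#' @param summary_a,summary_b `zone_summary` objects from [zone_fractions()]
#'   with matching zones.
#' @return Data frame: `zone`, `fraction_a`, `fraction_b`, `p`, `p_adj`,
#'   `method`. Zones empty in either condition get `NA` p-values (excluded
#'   from the adjustment).
#' @export
compare_zone_proportions <- function(summary_a, summary_b) {
  if (nrow(summary_a) != nrow(summary_b) ||
      any(summary_a$zone != summary_b$zone)) {
    stop("zone summaries do not match")
  }
  res <- do.call(rbind, lapply(seq_len(nrow(summary_a)), function(i) {
    a <- summary_a[i, ]
    b <- summary_b[i, ]
    if (a$n == 0 || b$n == 0) {
      return(data.frame(zone = a$zone, fraction_a = a$fraction,
                        fraction_b = b$fraction, p = NA_real_,
                        method = NA_character_))
    }
    tab <- matrix(c(a$n_true, a$n - a$n_true, b$n_true, b$n - b$n_true),
                  nrow = 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_fisher <- any(expected < 5) || any(colSums(tab) == 0)
    p <- if (use_fisher) {
      fisher.test(tab)$p.value
    } else {
      prop.test(tab, correct = TRUE)$p.value
    }
    data.frame(zone = a$zone, fraction_a = a$fraction, fraction_b = b$fraction,
               p = p, method = if (use_fisher) "fisher" else "prop")
  }))
  res$p_adj <- NA_real_
  ok <- !is.na(res$p)
  res$p_adj[ok] <- bh_adjust(res$p[ok])
  res[, c("zone", "fraction_a", "fraction_b", "p", "p_adj", "method")]
}
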