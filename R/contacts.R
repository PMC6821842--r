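#' Screen channels for visual responsiveness
#'
#' Per contact, the mean response of each exemplar in the response window is
#' tested against its baseline-window mean with a paired t-test across
#' exemplars, p-values are pooled across all contacts and FDR-corrected
#' (Benjamini-Hochberg), and effect size is Glass' delta - the mean
#' response-minus-baseline difference divided by the SD of the exemplar-mean
#' baseline values (the comparison distribution of the paired test). A
#' contact is visually responsive when `pFDR < alpha` and delta exceeds
#' `delta_min`. Contacts with degenerate baseline variance are flagged
#' untestable and excluded.
#'
#' @param ep Trial-level [epoch_and_normalize()] output whose trial table
#'   carries `stimulus_id`.
#' @param metadata Optional data.frame with per-contact `contact`, `patient`,
#'   `anatomical_label`, `depth_from_surface_mm` columns merged into the
#'   result.
#' @param alpha FDR level.
#' @param delta_min Glass' delta gate.
#' @param response_window,baseline_window Half-open windows in ms.
#' @return A `contact_table` data.frame: one row per contact with test
#'   statistics, `glass_delta` and `visual_flag`.
#' @export
detect_visual_contacts <- function(ep, metadata = NULL, alpha = 0.05,
                                   delta_min = 1,
                                   response_window = c(50, 500),
                                   baseline_window = c(-200, 0)) {
  trials <- attr(ep, "trials")
  time_ms <- attr(ep, "time_ms")
  rw <- time_ms >= response_window[1] & time_ms < response_window[2]
  bw <- time_ms >= baseline_window[1] & time_ms < baseline_window[2]
  ids <- sort(unique(trials$stimulus_id))
  if (length(ids) < 2) stop("need at least 2 exemplars")
  n_ch <- dim(ep)[2]
  res <- data.frame(contact = attr(ep, "channel_names"),
                    t = NA_real_, p = NA_real_, glass_delta = NA_real_,
                    untestable = FALSE, stringsAsFactors = FALSE)
  for (ch in seq_len(n_ch)) {
    resp <- base <- numeric(length(ids))
    for (i in seq_along(ids)) {
      rows <- trials$stimulus_id == ids[i]
      resp[i] <- mean(ep[rows, ch, rw])
      base[i] <- mean(ep[rows, ch, bw])
    }
    sd_base <- stats::sd(base)
    if (!is.finite(sd_base) || sd_base == 0 ||
        stats::sd(resp - base) == 0) {
      res$untestable[ch] <- TRUE
      next
    }
    tt <- stats::t.test(resp, base, paired = TRUE)
    res$t[ch] <- unname(tt$statistic)
    res$p[ch] <- tt$p.value
    res$glass_delta[ch] <- (mean(resp) - mean(base)) / sd_base
  }
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res$visual_flag <- !res$untestable & !is.na(res$p_fdr) &
    res$p_fdr < alpha & res$glass_delta > delta_min
  if (!is.null(metadata)) {
    res <- merge(res, metadata, by = "contact", all.x = TRUE, sort = FALSE)
    res <- res[match(attr(ep, "channel_names"), res$contact), ]
  }
  for (col in c("patient", "anatomical_label", "depth_from_surface_mm"))
    if (is.null(res[[col]]))
      res[[col]] <- if (col == "depth_from_surface_mm") NA_real_
                    else NA_character_
  rownames(res) <- NULL
  class(res) <- c("contact_table", "data.frame")
  res
}

#' Screen visually responsive contacts for face selectivity
#'
#' Applies, per visually responsive contact, two one-sided Wilcoxon rank-sum
#' tests on exemplar-mean responses - faces greater than each comparison
#' category (places and patterns, or the set's equivalents) - at uncorrected
#' `p < alpha`, plus anatomical constraints: contacts labelled V1, V2 or
#' frontal, or deeper than 10 mm from the cortical surface, are never face
#' contacts.
#'
#' @param contacts A `contact_table` from [detect_visual_contacts()].
#' @param ep The same epoched response used for screening.
#' @param face_category Category name of faces.
#' @param comparison_categories Two (or more) category names faces must beat.
#' @param alpha Per-test significance level (uncorrected).
#' @param excluded_regions Anatomical labels that veto face status.
#' @param max_depth_mm Depth gate in mm.
#' @param response_window Response window in ms.
#' @return The `contact_table` with `face_p_*` columns and `face_flag`.
#' @export
detect_face_contacts <- function(contacts, ep, face_category = "faces",
                                 comparison_categories = c("places",
                                                           "patterns"),
                                 alpha = 0.05,
                                 excluded_regions = c("V1", "V2", "frontal"),
                                 max_depth_mm = 10,
                                 response_window = c(50, 500)) {
  trials <- attr(ep, "trials")
  have <- unique(trials$category)
  missing <- setdiff(c(face_category, comparison_categories), have)
  if (length(missing))
    stop("protocol lacks required category: ",
         paste(missing, collapse = ", "))
  time_ms <- attr(ep, "time_ms")
  rw <- time_ms >= response_window[1] & time_ms < response_window[2]
  exemplar_means <- function(ch, cat) {
    ids <- unique(trials$stimulus_id[trials$category == cat])
    vapply(ids, function(id)
      mean(ep[trials$stimulus_id == id, ch, rw]), numeric(1))
  }
  n_ch <- dim(ep)[2]
  pmat <- matrix(NA_real_, n_ch, length(comparison_categories),
                 dimnames = list(NULL, comparison_categories))
  for (ch in seq_len(n_ch)) {
    if (!contacts$visual_flag[ch]) next
    fm <- exemplar_means(ch, face_category)
    for (cc in comparison_categories)
      pmat[ch, cc] <- stats::wilcox.test(fm, exemplar_means(ch, cc),
                                         alternative = "greater",
                                         exact = TRUE)$p.value
  }
  for (cc in comparison_categories)
    contacts[[paste0("face_p_", cc)]] <- pmat[, cc]
  anatomy_ok <- !(contacts$anatomical_label %in% excluded_regions) &
    !(is.finite(contacts$depth_from_surface_mm) &
        contacts$depth_from_surface_mm > max_depth_mm)
  contacts$face_flag <- contacts$visual_flag &
    apply(pmat < alpha, 1, function(z) all(!is.na(z) & z)) &
    anatomy_ok
  contacts
}

#' Exemplar selectivity index of one face contact
#'
#' The d-prime between a contact's most- and least-preferred face exemplars:
#' with mu and sigma^2 the mean and variance over repetitions of the mean
#' response in the analysis window,
#' `(mu_best - mu_worst) / sqrt((sigma2_best + sigma2_worst) / 2)`.
#' Significance is a permutation test: single-trial exemplar labels are
#' shuffled `n_perm` times, the index recomputed each time (re-selecting the
#' extreme exemplars), and p is the proportion of shuffled indices exceeding
#' the observed one.
#'
#' @param G A [build_response_matrix()] array.
#' @param contact Contact id or index into the matrix.
#' @param n_perm Number of label shuffles.
#' @param seed Integer seed.
#' @return List with `index`, `p`, `best`, `worst`.
#' @export
exemplar_selectivity_index <- function(G, contact, n_perm = 1000,
                                       seed = 1L) {
  if (is.character(contact))
    contact <- match(contact, attr(G, "contact_ids"))
  x <- apply(G[, contact, , , drop = FALSE], c(1, 3), mean)  # exemplar x rep
  vals <- lapply(seq_len(nrow(x)), function(e) x[e, !is.na(x[e, ])])
  if (any(vapply(vals, length, 1L) < 2))
    stop("need at least 2 repetitions per exemplar")
  index_of <- function(vals) {
    mu <- vapply(vals, mean, numeric(1))
    s2 <- vapply(vals, stats::var, numeric(1))
    b <- which.max(mu); w <- which.min(mu)
    if (s2[b] + s2[w] == 0)
      stop("selectivity index undefined: zero variance in both extremes")
    list(idx = (mu[b] - mu[w]) / sqrt((s2[b] + s2[w]) / 2), b = b, w = w)
  }
  obs <- index_of(vals)
  set.seed(seed)
  pool <- unlist(vals)
  sizes <- vapply(vals, length, 1L)
  null <- vapply(seq_len(n_perm), function(i) {
    shuffled <- split(sample(pool), rep(seq_along(sizes), sizes))
    index_of(shuffled)$idx
  }, numeric(1))
  list(index = obs$idx, p = mean(null > obs$idx),
       best = obs$b, worst = obs$w)
}

#' Assemble the grand response matrix G
#'
#' Orders face-contact responses into the 4-D array
#' exemplars x contacts x repetition trials x time, each cell a response time
#' series over the `[50, 500)` ms window, optionally smoothed with a running
#' average (50 ms for decoding input; disable with `smoothing_ms = 0` for
#' representational analyses). Missing repetitions are `NA`, never
#' zero-filled.
#'
#' @param ep Trial-level epoched response (percent signal change HFA).
#' @param contacts Optional `contact_table`; when given, only contacts with
#'   `face_flag` are included.
#' @param smoothing_ms Running-average window in ms (0 = none).
#' @param window Half-open response window in ms.
#' @param category Stimulus category entering the matrix.
#' @return Object of class `response_matrix` with `exemplar_ids`,
#'   `contact_ids`, `time_ms` and `smoothing_ms` attributes.
#' @export
build_response_matrix <- function(ep, contacts = NULL, smoothing_ms = 50,
                                  window = c(50, 500), category = "faces") {
  trials <- attr(ep, "trials")
  time_ms <- attr(ep, "time_ms")
  keep_ch <- if (is.null(contacts)) seq_len(dim(ep)[2])
             else which(contacts$face_flag)
  if (!length(keep_ch)) stop("no face contacts to assemble")
  tw <- time_ms >= window[1] & time_ms < window[2]
  face_rows <- which(trials$category == category)
  ids <- sort(unique(trials$stimulus_id[face_rows]))
  reps <- max(table(trials$stimulus_id[face_rows]))
  if (any(table(trials$stimulus_id[face_rows]) == 0))
    stop("contact with zero trials for some exemplar")
  G <- array(NA_real_, c(length(ids), length(keep_ch), reps, sum(tw)))
  step_ms <- diff(time_ms)[1]
  k <- if (smoothing_ms > 0) max(1L, round(smoothing_ms / step_ms)) else 1L
  for (e in seq_along(ids)) {
    rows <- face_rows[trials$stimulus_id[face_rows] == ids[e]]
    for (r in seq_along(rows)) {
      for (ci in seq_along(keep_ch)) {
        series <- ep[rows[r], keep_ch[ci], tw]
        G[e, ci, r, ] <- if (k > 1L) moving_average(series, k) else series
      }
    }
  }
  structure(G, exemplar_ids = ids,
            contact_ids = attr(ep, "channel_names")[keep_ch],
            time_ms = time_ms[tw], smoothing_ms = smoothing_ms,
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(paste0("response_matrix G: %d exemplars x %d contacts x %d ",
                     "reps x %d samples (smoothing %g ms)\n"),
              d[1], d[2], d[3], d[4], attr(x, "smoothing_ms")))
  invisible(x)
}

#' Construct a response matrix directly from trial-level cell values
#'
#' Convenience constructor for synthetic pattern data: takes an array
#' exemplars x contacts x reps (x time) and wraps it as a `response_matrix`.
#'
#' @param arr Array with 3 or 4 dimensions (a 3-D array gets a singleton
#'   time axis).
#' @param exemplar_ids,contact_ids Optional ids.
#' @param time_ms Time axis in ms.
#' @return A `response_matrix`.
#' @export
as_response_matrix <- function(arr, exemplar_ids = NULL, contact_ids = NULL,
                               time_ms = NULL) {
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
  d <- dim(arr)
  structure(arr,
            exemplar_ids = exemplar_ids %||% sprintf("face_%02d",
                                                     seq_len(d[1])),
            contact_ids = contact_ids %||% sprintf("c%03d", seq_len(d[2])),
            time_ms = time_ms %||% seq(50, by = 2, length.out = d[4]),
            smoothing_ms = 0,
            class = "response_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
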