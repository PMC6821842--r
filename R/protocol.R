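#' Construct a 1-back task protocol object
#'
#' A protocol is an ordered trial table for one version of the 1-back visual
#' task, plus stimulus timing metadata. Most users will call
#' [generate_protocol()] rather than this constructor.
#'
#' @param trials data.frame with columns `onset_ms`, `stimulus_id`, `category`,
#'   `is_repeat` and (optionally) `block_id`, one row per trial in order.
#' @param set_id Task version, 1, 2 or 3.
#' @param stimulus_duration_ms Presentation duration in ms.
#' @param n_stimuli_per_category Named integer vector, stimuli per category.
#' @return An object of class `task_protocol` (a data.frame with attributes).
#' @export
task_protocol <- function(trials, set_id, stimulus_duration_ms,
                          n_stimuli_per_category) {
  stopifnot(is.data.frame(trials),
            all(c("onset_ms", "stimulus_id", "category", "is_repeat") %in%
                  names(trials)))
  if (is.unsorted(trials$onset_ms, strictly = TRUE))
    stop("trial onsets must be strictly increasing")
  declared <- trials$is_repeat
  actual <- c(FALSE, trials$stimulus_id[-1] == trials$stimulus_id[-nrow(trials)])
  if (!identical(as.logical(declared), actual))
    stop("is_repeat flags must mark exactly the immediate 1-back repetitions")
  structure(trials,
            set_id = as.integer(set_id),
            stimulus_duration_ms = stimulus_duration_ms,
            n_stimuli_per_category = n_stimuli_per_category,
            class = c("task_protocol", "data.frame"))
}

#' @export
print.task_protocol <- function(x, ...) {
  cat(sprintf("task_protocol: set %d, %d trials, %d repeats, %d ms stimuli\n",
              attr(x, "set_id"), nrow(x), sum(x$is_repeat),
              attr(x, "stimulus_duration_ms")))
  invisible(x)
}

# stimulus inventory per task version; counts per category are fixed by the
# printed totals (60 / 56 / 50 stimuli).
protocol_inventory <- function(set_id) {
  switch(as.character(set_id),
    "1" = c(faces = 10, animals = 10, tools = 10, words = 10,
            patterns = 10, places = 10),
    "2" = c(faces = 10, tools = 12, patterns = 12, houses = 12,
            body_parts = 10),
    "3" = c(faces = 10, tools = 10, patterns = 10, houses = 10,
            body_parts = 10),
    stop("unknown set_id: ", set_id))
}

# Shuffle a multiset of ids so that no two equal ids are adjacent; repairs
# collisions by swapping with a compatible position.
shuffle_no_adjacent <- function(ids) {
  x <- sample(ids)
  for (pass in 1:50) {
    bad <- which(x[-1] == x[-length(x)]) + 1L
    if (!length(bad)) return(x)
    for (i in bad) {
      ok <- which(x != x[i] &
                    c(x[-1], NA) != x[i] &
                    c(NA, x[-length(x)]) != x[i])
      ok <- setdiff(ok, c(i - 1L, i, i + 1L))
      ok <- ok[!is.na(ok)]
      if (length(ok)) {
        j <- sample(ok, 1)
        tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
      }
    }
    x <- if (any(x[-1] == x[-length(x)])) sample(ids) else x
  }
  stop("could not arrange stimuli without accidental repetitions")
}

# Insert one immediate repetition after a random occurrence of each id in
# `rep_ids`; the sequence is assumed free of adjacent duplicates beforehand.
insert_repeats <- function(seq_ids, rep_ids) {
  for (id in rep_ids) {
    pos <- which(seq_ids == id)
    at <- if (length(pos) == 1L) pos else sample(pos, 1)
    seq_ids <- append(seq_ids, id, after = at)
  }
  seq_ids
}

#' Generate a pseudo-random 1-back task protocol
#'
#' Builds a trial sequence for one of the three task versions with the
#' version's fixed structure: set 1 has 360 trials (60 stimuli presented six
#' times each, counting repeats) with 24 immediate 1-back repetitions, 250 ms
#' stimuli and 750-1050 ms jittered inter-stimulus intervals; set 2 has 205
#' trials (56 stimuli, 37 shown four times and 19 three times), 25 repetitions
#' and a fixed 1 Hz pace; set 3 has 260 trials in 26 ten-trial single-category
#' blocks with 18 repetitions, 500 ms stimuli, 750-1500 ms jitter and 4 or 8 s
#' gaps between blocks.
#'
#' Repeated presentations count toward each stimulus' presentation quota (the
#' set-1 arithmetic 360 = 60 x 6 forces this). Repeats are placed uniformly
#' among eligible stimuli.
#'
#' @param set_id Task version, 1, 2 or 3.
#' @param seed Integer seed; the sequence is reproducible from it.
#' @return A [task_protocol()].
#' @export
generate_protocol <- function(set_id, seed = 1L) {
  set.seed(seed)
  inv <- protocol_inventory(set_id)
  stim <- unlist(lapply(names(inv), function(cat)
    sprintf("%s_%02d", sub("s$", "", cat), seq_len(inv[[cat]]))))
  stim_cat <- rep(names(inv), inv)
  names(stim_cat) <- stim

  if (set_id %in% c(1, 2)) {
    if (set_id == 1) {
      quota <- stats::setNames(rep(6L, length(stim)), stim)
      n_rep <- 24L; dur <- 250L
      isi <- function(n) stats::runif(n, 750, 1050)
    } else {
      quota <- stats::setNames(rep(3L, length(stim)), stim)
      quota[sample(stim, 37)] <- 4L   # 37 x 4 + 19 x 3 = 205
      n_rep <- 25L; dur <- 250L
      isi <- NULL                     # fixed 1 Hz pace
    }
    rep_ids <- sample(stim, n_rep)
    base <- rep(names(quota), quota - as.integer(names(quota) %in% rep_ids))
    seq_ids <- insert_repeats(shuffle_no_adjacent(base), rep_ids)
    block <- rep(NA_integer_, length(seq_ids))
  } else {
    # 26 single-category ten-trial blocks; category block counts 6+5+5+5+5.
    n_blocks_cat <- stats::setNames(c(6L, 5L, 5L, 5L, 5L),
                                    sample(names(inv)))
    # schedule block categories with no two alike in a row: when one
    # category holds more than half the remaining slots it must go next,
    # otherwise draw weighted by remaining count
    remaining <- n_blocks_cat
    blocks_cat <- character(26L)
    prev <- ""
    for (b in seq_len(26L)) {
      avail <- remaining[names(remaining) != prev & remaining > 0]
      slots_left <- 26L - b + 1L
      nm <- names(avail)
      pick <- if (max(avail) >= ceiling(slots_left / 2)) {
        top <- nm[avail == max(avail)]
        top[sample.int(length(top), 1L)]
      } else {
        nm[sample.int(length(nm), 1L, prob = avail)]
      }
      blocks_cat[b] <- pick
      remaining[pick] <- remaining[pick] - 1L
      prev <- pick
    }
    rep_blocks <- sort(sample(26L, 18L))
    seq_ids <- character(0); block <- integer(0)
    for (b in seq_len(26L)) {
      ex <- stim[stim_cat == blocks_cat[b]]
      if (b %in% rep_blocks) {
        # balance presentation totals: the most-presented exemplar so far
        # sits this block out, the least-presented is the 1-back repeat
        pick1 <- function(x) x[sample.int(length(x), 1L)]
        cnt <- vapply(ex, function(e) sum(seq_ids == e), integer(1))
        omit <- pick1(ex[cnt == max(cnt)])
        present <- setdiff(ex, omit)
        ord <- sample(present)
        cnt_p <- cnt[match(present, ex)]
        rep_id <- pick1(present[cnt_p == min(cnt_p)])
        at <- which(ord == rep_id)
        ord <- append(ord, rep_id, after = at)
      } else {
        ord <- sample(ex)
      }
      seq_ids <- c(seq_ids, ord)
      block <- c(block, rep(b, 10L))
    }
    dur <- 500L
    isi <- function(n) stats::runif(n, 750, 1500)
  }

  # 2 s lead-in before the first trial so baselines fit inside the recording
  n <- length(seq_ids)
  if (set_id == 2) {
    onsets <- 2000 + (seq_len(n) - 1L) * 1000
  } else {
    soa <- dur + isi(n - 1L)
    if (set_id == 3) {
      gaps <- sample(c(4000, 8000), 25L, replace = TRUE)
      boundary <- which(diff(block) != 0)
      soa[boundary] <- soa[boundary] + gaps
    }
    onsets <- 2000 + cumsum(c(0, soa))
  }
  trials <- data.frame(
    onset_ms = as.integer(round(onsets)),
    stimulus_id = seq_ids,
    category = unname(stim_cat[seq_ids]),
    is_repeat = c(FALSE, seq_ids[-1] == seq_ids[-n]),
    block_id = if (set_id == 3) block else NA_integer_,
    stringsAsFactors = FALSE)
  task_protocol(trials, set_id, dur, inv)
}

#' Write / read a protocol as a BIDS-style events table
#'
#' Columns: onset (ms), duration (ms), trial_type (category), stimulus_id,
#' category, is_repeat, block_id; tab-separated.
#'
#' @param protocol A [task_protocol()].
#' @param path Output TSV path.
#' @return `path`, invisibly (`read_events_tsv` returns a `task_protocol`).
#' @export
write_events_tsv <- function(protocol, path) {
  out <- data.frame(onset = protocol$onset_ms,
                    duration = attr(protocol, "stimulus_duration_ms"),
                    trial_type = protocol$category,
                    stimulus_id = protocol$stimulus_id,
                    category = protocol$category,
                    is_repeat = as.integer(protocol$is_repeat),
                    block_id = protocol$block_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param set_id Task version recorded in the returned object.
#' @export
read_events_tsv <- function(path, set_id = NA_integer_) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  trials <- data.frame(onset_ms = tab$onset,
                       stimulus_id = tab$stimulus_id,
                       category = tab$category,
                       is_repeat = as.logical(tab$is_repeat),
                       block_id = tab$block_id,
                       stringsAsFactors = FALSE)
  inv <- table(tab$category[!duplicated(tab$stimulus_id)])
  task_protocol(trials, set_id, tab$duration[1],
                stats::setNames(as.integer(inv), names(inv)))
}
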