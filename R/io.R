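# Sequence serialization: JSON (canonical, round-trips every field) and a
# long-format CSV (frame, dot, label, x, y) for spreadsheet-style use.

#' Read and write point-light sequences
#'
#' The JSON dialect is an object with fields `action_name`,
#' `frame_duration_s`, `is_cyclic`, `dot_labels` and `frames`, the latter a
#' `T x D x 2` nested array. Coordinates are written at full precision, so
#' write-then-read is the identity. The CSV format stores one row per
#' (frame, dot) with metadata repeated in `action_name` and
#' `frame_duration_s` columns.
#'
#' @param seq a [pl_sequence()].
#' @param path file path; extension `.json` or `.csv` selects the format.
#' @return `read_sequence()` returns a [pl_sequence()];
#'   `write_sequence()` returns `path` invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "pl_sequence"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- dim(seq$positions)
    df <- data.frame(
      frame = rep(seq_len(d[1]), times = d[2]),
      dot = rep(seq_len(d[2]), each = d[1]),
      label = rep(seq$dot_labels, each = d[1]),
      x = as.vector(seq$positions[, , 1]),
      y = as.vector(seq$positions[, , 2]),
      action_name = seq$action_name,
      frame_duration_s = seq$frame_duration_s)
    utils::write.csv(df[order(df$frame, df$dot), ], path, row.names = FALSE)
  } else {
    frames <- lapply(seq_len(dim(seq$positions)[1]), function(t)
      lapply(seq_len(dim(seq$positions)[2]), function(i)
        seq$positions[t, i, ]))
    jsonlite::write_json(
      list(action_name = seq$action_name,
           frame_duration_s = seq$frame_duration_s,
           is_cyclic = seq$is_cyclic,
           dot_labels = seq$dot_labels,
           frames = frames),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    need <- c("frame", "dot", "x", "y")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("malformed sequence CSV: missing field(s) ", paste(miss, collapse = ", "))
    if (!is.numeric(df$x) || !is.numeric(df$y))
      stop("malformed sequence CSV: non-numeric coordinate in field 'x'/'y'")
    Tn <- max(df$frame); D <- max(df$dot)
    counts <- table(df$frame)
    if (length(unique(counts)) != 1L || nrow(df) != Tn * D)
      stop("malformed sequence CSV: field 'frames' has unequal dot counts across frames")
    pos <- array(NA_real_, c(Tn, D, 2))
    pos[cbind(df$frame, df$dot, 1L)] <- df$x
    pos[cbind(df$frame, df$dot, 2L)] <- df$y
    if (anyNA(pos)) stop("malformed sequence CSV: incomplete (frame, dot) grid")
    labels <- if ("label" %in% names(df))
      df$label[order(df$frame, df$dot)][seq_len(D)] else NULL
    pl_sequence(pos,
                frame_duration_s = if ("frame_duration_s" %in% names(df))
                  df$frame_duration_s[1] else 0.05,
                dot_labels = labels,
                action_name = if ("action_name" %in% names(df))
                  as.character(df$action_name[1]) else "csv")
  } else {
    obj <- jsonlite::read_json(path)
    for (f in c("action_name", "frame_duration_s", "dot_labels", "frames"))
      if (is.null(obj[[f]]))
        stop("malformed sequence file: missing field '", f, "'")
    D <- length(obj$dot_labels)
    Tn <- length(obj$frames)
    pos <- array(NA_real_, c(Tn, D, 2))
    for (t in seq_len(Tn)) {
      fr <- obj$frames[[t]]
      if (length(fr) != D)
        stop(sprintf(
          "malformed sequence file: field 'frames' frame %d has %d dots, expected %d",
          t, length(fr), D))
      for (i in seq_len(D)) {
        xy <- unlist(fr[[i]])
        if (length(xy) != 2L || !is.numeric(xy))
          stop(sprintf(
            "malformed sequence file: non-numeric coordinate in field 'frames', frame %d dot %d",
            t, i))
        pos[t, i, ] <- xy
      }
    }
    pl_sequence(pos, obj$frame_duration_s,
                dot_labels = unlist(obj$dot_labels),
                action_name = obj$action_name,
                is_cyclic = isTRUE(obj$is_cyclic))
  }
}
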