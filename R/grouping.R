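# Grouping of per-template nominations into reviewed IED candidates.
# Two passes: same-channel merging (single linkage on >75% interval
# overlap), discard of groups with fewer than three member nominations,
# then a cross-channel merge of groups whose onsets fall within one second
# of the earliest group.

# union-find with path halving
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Merge nominations on the same channel
#'
#' Single-linkage clustering per (montage, channel): two nominations link
#' when their intervals overlap by more than `min_overlap` of the shorter
#' interval (strict inequality). Every input nomination ends up in exactly
#' one channel group.
#'
#' @param noms Nomination tibble from one recording.
#' @param min_overlap Overlap fraction threshold (default 0.75).
#' @return Channel-group tibble: `channel_group`, `montage`, `channel`,
#'   `start`, `end`, `n_members`, and list-column `members` holding the
#'   member nomination rows.
#' @export
merge_same_channel <- function(noms, min_overlap = 0.75) {
  if (!nrow(noms)) {
    return(tibble::tibble(
      channel_group = character(), montage = character(),
      channel = character(), start = integer(), end = integer(),
      n_members = integer(), members = list()
    ))
  }
  noms <- dplyr::arrange(noms, .data$montage, .data$channel, .data$start,
                         .data$template_id)
  key <- paste(noms$montage, noms$channel)
  gid <- 0L
  out <- list()
  for (k in unique(key)) {
    sub <- noms[key == k, ]
    n <- nrow(sub)
    a <- sub$start
    b <- sub$start + sub$length
    parent <- seq_len(n)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          ov <- min(b[i], b[j]) - max(a[i], a[j])
          if (ov > min_overlap * min(sub$length[i], sub$length[j])) {
            ri <- .uf_find(parent, i)
            rj <- .uf_find(parent, j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
    }
    roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
    for (r in unique(roots)) {
      gid <- gid + 1L
      mem <- sub[roots == r, ]
      out[[gid]] <- tibble::tibble(
        channel_group = sprintf("cg-%04d", gid),
        montage = mem$montage[1], channel = mem$channel[1],
        start = min(mem$start), end = max(mem$start + mem$length),
        n_members = nrow(mem), members = list(mem)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Discard channel groups with too few member nominations
#'
#' @param groups Channel-group tibble from [merge_same_channel()].
#' @param min_members Minimum member count to keep (default 3).
#' @return Filtered channel-group tibble.
#' @export
filter_small_groups <- function(groups, min_members = 3) {
  dplyr::filter(groups, .data$n_members >= min_members)
}

#' Merge channel groups across channels into IED nominations
#'
#' Groups are sorted by onset; the earliest unmerged group seeds an IED
#' nomination, and every later group whose onset starts strictly less than
#' `window_s` after the seed's onset joins it. Member nominations are
#' concatenated, the interval is the union, the channel set the union.
#'
#' @param groups Filtered channel-group tibble.
#' @param window_s Onset merge window in seconds (default 1).
#' @param sample_rate Samples per second of the nomination sample indices.
#' @return Grouped-nomination tibble: `group_id`, `start`, `end`,
#'   `onset_s`, `duration_s`, `channels` (list), `n_members`, `members`
#'   (list of nomination rows), `status` (all `"pending"`).
#' @export
merge_across_channels <- function(groups, window_s = 1, sample_rate = 100) {
  empty <- tibble::tibble(
    group_id = character(), start = integer(), end = integer(),
    onset_s = numeric(), duration_s = numeric(), channels = list(),
    n_members = integer(), members = list(), status = character()
  )
  if (!nrow(groups)) return(empty)
  groups <- dplyr::arrange(groups, .data$start, .data$channel_group)
  win <- window_s * sample_rate
  taken <- rep(FALSE, nrow(groups))
  out <- list()
  gid <- 0L
  for (i in seq_len(nrow(groups))) {
    if (taken[i]) next
    join <- which(!taken & groups$start >= groups$start[i] &
                    groups$start - groups$start[i] < win)
    taken[join] <- TRUE
    mem <- dplyr::bind_rows(groups$members[join])
    gid <- gid + 1L
    out[[gid]] <- tibble::tibble(
      group_id = sprintf("grp-%04d", gid),
      start = min(groups$start[join]), end = max(groups$end[join]),
      onset_s = min(groups$start[join]) / sample_rate,
      duration_s = (max(groups$end[join]) - min(groups$start[join])) /
        sample_rate,
      channels = list(sort(unique(mem$channel))),
      n_members = nrow(mem), members = list(mem),
      status = "pending"
    )
  }
  dplyr::bind_rows(out)
}

#' Group certainty from member correlations and reliabilities
#'
#' Aggregates each member nomination's evidence `c_i * r_i` (correlation
#' clamped to \[0, 1\] times template reliability) into one certainty in
#' \[0, 1\]. The default noisy-OR, `1 - prod(1 - c_i r_i)`, treats members
#' as independent corroborating evidence, so certainty never decreases when
#' a member is added or a reliability rises.
#'
#' @param correlation,rel Equal-length numeric vectors over group members.
#' @param aggregator One of `"noisy_or"`, `"mean"`, `"max"`.
#' @return Certainty scalar in \[0, 1\].
#' @export
certainty_value <- function(correlation, rel,
                            aggregator = c("noisy_or", "mean", "max")) {
  aggregator <- match.arg(aggregator)
  if (!length(correlation)) stop("certainty of an empty group is undefined")
  p <- pmin(1, pmax(0, correlation)) * rel
  switch(aggregator,
    noisy_or = -expm1(sum(log1p(-pmin(p, 1 - 1e-15)))),
    mean = mean(p),
    max = max(p)
  )
}

#' Recompute the certainty of each group
#'
#' @param groups Grouped-nomination tibble.
#' @param rel Named reliability vector by `template_id`; when `NULL` the
#'   reliabilities stamped on the member nominations are used.
#' @param aggregator Certainty aggregator name.
#' @return `groups` with a `certainty` column.
#' @export
group_certainty <- function(groups, rel = NULL, aggregator = "noisy_or") {
  groups$certainty <- vapply(groups$members, function(mem) {
    r <- if (is.null(rel)) mem$reliability else unname(rel[mem$template_id])
    certainty_value(mem$correlation, r, aggregator)
  }, numeric(1))
  groups
}

#' Full grouping pipeline: nominations to certainty-ranked IED groups
#'
#' Applies same-channel merging, the minimum-member filter, cross-channel
#' merging and certainty calculation in order.
#'
#' @param noms Nomination tibble from one recording.
#' @param db Optional `ied_template_db` providing current reliabilities;
#'   when `NULL` the reliabilities stamped on the nominations are used.
#' @param min_overlap,min_members,window_s Grouping parameters.
#' @param aggregator Certainty aggregator name.
#' @return Grouped-nomination tibble with certainties, sorted by descending
#'   certainty.
#' @export
group_nominations <- function(noms, db = NULL, min_overlap = 0.75,
                              min_members = 3, window_s = 1,
                              aggregator = "noisy_or") {
  rel <- if (!is.null(db)) db_reliabilities(db) else NULL
  merge_same_channel(noms, min_overlap = min_overlap) |>
    filter_small_groups(min_members = min_members) |>
    merge_across_channels(window_s = window_s) |>
    group_certainty(rel = rel, aggregator = aggregator) |>
    dplyr::arrange(dplyr::desc(.data$certainty), .data$onset_s,
                   .data$group_id)
}

#' Write / read grouped nominations as CSV
#'
#' The flat on-disk form carries the group summary (member nominations are
#' re-derivable from the nominations file).
#'
#' @param groups Grouped-nomination tibble.
#' @param path CSV path.
#' @return `path` (write) or a summary tibble (read).
#' @export
write_groups <- function(groups, path) {
  flat <- dplyr::mutate(
    dplyr::select(groups, "group_id", "onset_s", "duration_s",
                  "n_members", "certainty", "status"),
    channels = vapply(groups$channels, paste, character(1), collapse = ";")
  )
  utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$channels <- strsplit(df$channels, ";", fixed = TRUE)
  tibble::as_tibble(df)
}
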