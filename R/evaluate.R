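#' Benchmark manifest: shapes and their conformer groups
#'
#' Maps shape ids to files (optional) and group labels; a group gathers the
#' conformers of one flexible molecule, and retrieval quality is measured by
#' how early a query's group mates are ranked.
#'
#' @param ids character vector of unique shape ids.
#' @param groups character vector of group labels, one per id.
#' @param paths optional file paths, one per id.
#' @return Object of class `benchmark_manifest` (a data.frame with columns
#'   `id`, `group`, `path`).
#' @export
benchmark_manifest <- function(ids, groups, paths = NA_character_) {
  ids <- as.character(ids)
  groups <- as.character(groups)
  if (length(ids) != length(groups)) {
    stop("'ids' and 'groups' must have equal length", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("shape ids must be unique", call. = FALSE)
  if (any(!nzchar(groups)) || anyNA(groups)) {
    stop("every entry needs a nonempty group label", call. = FALSE)
  }
  structure(
    data.frame(id = ids, group = groups,
               path = rep_len(as.character(paths), length(ids)),
               stringsAsFactors = FALSE),
    class = c("benchmark_manifest", "data.frame")
  )
}

#' Read / write a manifest as tab-separated text (id, path, group)
#' @param path TSV file path.
#' @param manifest a [benchmark_manifest()].
#' @return The manifest (reader) or `path` invisibly (writer).
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id", "path", "group"))
  benchmark_manifest(df$id, df$group, df$path)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "benchmark_manifest"))
  utils::write.table(manifest[, c("id", "path", "group")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

manifest_group_of <- function(manifest, id) {
  g <- manifest$group[match(id, manifest$id)]
  if (is.na(g)) stop("id '", id, "' not in manifest", call. = FALSE)
  g
}

#' Rank a descriptor database against a query
#'
#' Scores every database descriptor against the query and sorts ascending by
#' dissimilarity, ties broken by id in lexicographic order (deterministic).
#' If the query id itself appears in the database it is excluded.
#'
#' @param query a `shape_descriptor`.
#' @param db named list of `shape_descriptor`s (names are shape ids).
#' @param metric histogram metric, see [compare_descriptors()].
#' @param query_id id of the query (to exclude it from the database ranking).
#' @return Object of class `retrieval_run`: `query_id`, `ranked_ids`,
#'   `scores` (non-decreasing).
#' @export
rank_database <- function(query, db, metric = "L1", query_id = NULL) {
  stopifnot(inherits(query, "shape_descriptor"), is.list(db))
  if (is.null(names(db)) || any(!nzchar(names(db)))) {
    stop("'db' must be a named list of descriptors", call. = FALSE)
  }
  if (!is.null(query_id)) db <- db[setdiff(names(db), query_id)]
  if (length(db) == 0L) stop("empty database", call. = FALSE)
  scores <- vapply(db, compare_descriptors, numeric(1L), a = query,
                   metric = metric)
  ord <- order(scores, names(db), method = "radix")
  structure(
    list(query_id = query_id %||% NA_character_,
         ranked_ids = names(db)[ord], scores = unname(scores[ord]),
         metric = metric),
    class = "retrieval_run"
  )
}

relevant_count <- function(run, manifest) {
  grp <- manifest_group_of(manifest, run$query_id)
  sum(manifest$group == grp & manifest$id != run$query_id)
}

#' Precision-recall curve of one retrieval run
#'
#' At retrieval size `s`, precision = TP / s and recall = TP / R where R is
#' the number of database shapes sharing the query's group (the query itself
#' is excluded from both the database and the relevant set).
#'
#' @param run a [rank_database()] result with a `query_id`.
#' @param manifest a [benchmark_manifest()].
#' @return data.frame with columns `size`, `precision`, `recall`; `NULL` with
#'   a warning for a singleton-group query (recall undefined).
#' @export
precision_recall <- function(run, manifest) {
  stopifnot(inherits(run, "retrieval_run"))
  nrel <- relevant_count(run, manifest)
  if (nrel == 0L) {
    warning("query '", run$query_id,
            "' is the only member of its group; skipped", call. = FALSE)
    return(NULL)
  }
  grp <- manifest_group_of(manifest, run$query_id)
  hit <- manifest$group[match(run$ranked_ids, manifest$id)] == grp
  tp <- cumsum(hit)
  s <- seq_along(hit)
  data.frame(size = s, precision = tp / s, recall = tp / nrel)
}

#' Average precision over queries at fixed recall levels
#'
#' Each query's precision is linearly interpolated over its recall range
#' (using, at every distinct recall value, the precision of the smallest
#' retrieval size attaining it) and the interpolated curves are averaged.
#'
#' @param runs list of [rank_database()] results.
#' @param manifest a [benchmark_manifest()].
#' @param recall_levels recall grid in [0, 1].
#' @return data.frame with columns `recall`, `precision`.
#' @export
average_pr <- function(runs, manifest, recall_levels = seq(0, 1, by = 0.05)) {
  curves <- lapply(runs, function(run) {
    pr <- precision_recall(run, manifest)
    if (is.null(pr)) return(NULL)
    first <- !duplicated(pr$recall)
    r <- pr$recall[first]
    p <- pr$precision[first]
    if (r[1L] > 0) {  # anchor at recall 0 with the first precision value
      r <- c(0, r)
      p <- c(p[1L], p)
    }
    stats::approx(r, p, xout = recall_levels, rule = 2)$y
  })
  curves <- curves[!vapply(curves, is.null, logical(1L))]
  if (!length(curves)) stop("no usable queries", call. = FALSE)
  data.frame(recall = recall_levels,
             precision = colMeans(do.call(rbind, curves)))
}

precision_recall_at <- function(run, manifest, size) {
  nrel <- relevant_count(run, manifest)
  if (nrel == 0L) return(NULL)
  s <- min(size, length(run$ranked_ids))
  grp <- manifest_group_of(manifest, run$query_id)
  tp <- sum(manifest$group[match(run$ranked_ids[seq_len(s)], manifest$id)] == grp)
  c(precision = tp / s, recall = tp / nrel)
}

harmonic_mean2 <- function(p, r) {
  p <- unname(p)
  r <- unname(r)
  if (p + r <= 0) 0 else 2 * p * r / (p + r)
}

#' E-measure of a retrieval run
#'
#' Harmonic composite `2 / (1/precision + 1/recall)` of precision and recall
#' at a fixed retrieval size of 64 (or the database size if smaller); scores
#' lie in [0, 1] and the convention E = 0 applies when precision and recall
#' are both zero.
#'
#' @param run a [rank_database()] result.
#' @param manifest a [benchmark_manifest()].
#' @param size retrieval size (default 64).
#' @return E-measure in [0, 1], or `NA` for a singleton-group query.
#' @export
e_measure <- function(run, manifest, size = 64L) {
  pr <- precision_recall_at(run, manifest, size)
  if (is.null(pr)) return(NA_real_)
  harmonic_mean2(pr["precision"], pr["recall"])
}

#' F-measure of a retrieval run
#'
#' Harmonic mean of precision and recall at a given retrieval size; defaults
#' to the query's relevant-set size (group size minus one), so perfect
#' retrieval scores 1.
#'
#' @param run a [rank_database()] result.
#' @param manifest a [benchmark_manifest()].
#' @param size retrieval size; `NULL` (default) uses the relevant-set size.
#' @return F-measure in [0, 1], or `NA` for a singleton-group query.
#' @export
f_measure <- function(run, manifest, size = NULL) {
  nrel <- relevant_count(run, manifest)
  if (nrel == 0L) return(NA_real_)
  pr <- precision_recall_at(run, manifest, size %||% nrel)
  harmonic_mean2(pr["precision"], pr["recall"])
}

#' Retrieval statistics over all queries of a descriptor database
#'
#' Uses every database shape in turn as the query against the remaining
#' shapes and averages nearest-neighbour accuracy (is the top-ranked shape in
#' the query's group?), E-measure and F-measure over the usable queries.
#'
#' @param db named list of `shape_descriptor`s.
#' @param manifest a [benchmark_manifest()] covering the db ids.
#' @param metric histogram metric (default `"L1"`).
#' @param e_size retrieval size for the E-measure (default 64).
#' @return list with `nn_accuracy`, `e_measure`, `f_measure`, `runs`.
#' @export
retrieval_statistics <- function(db, manifest, metric = "L1", e_size = 64L) {
  runs <- lapply(names(db), function(id) {
    rank_database(db[[id]], db, metric = metric, query_id = id)
  })
  names(runs) <- names(db)
  usable <- vapply(runs, function(r) relevant_count(r, manifest) > 0L, logical(1L))
  if (!any(usable)) stop("no query has group mates", call. = FALSE)
  nn <- vapply(runs[usable], function(r) {
    manifest_group_of(manifest, r$ranked_ids[1L]) ==
      manifest_group_of(manifest, r$query_id)
  }, logical(1L))
  em <- vapply(runs[usable], e_measure, numeric(1L), manifest = manifest,
               size = e_size)
  fm <- vapply(runs[usable], f_measure, numeric(1L), manifest = manifest)
  list(nn_accuracy = mean(nn), e_measure = mean(em), f_measure = mean(fm),
       runs = runs)
}
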