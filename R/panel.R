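# The panel_dataset container: participants x nodes x waves, plus wide-CSV
# round-tripping with a JSON sidecar for the node scheme.

#' Construct a panel dataset
#'
#' @param values numeric array, participants x nodes x waves, with
#'   dimnames (participant ids, node ids, wave labels).
#' @param scheme the \code{node_scheme} the node dimension follows.
#' @param missing_mask optional logical array of the same shape; TRUE
#'   marks a cell as missing (the underlying value is retained).
#' @return An object of class \code{panel_dataset}.
#' @export
panel_dataset <- function(values, scheme, missing_mask = NULL) {
  validate_scheme(scheme)
  stopifnot(is.array(values), length(dim(values)) == 3L)
  dn <- dimnames(values)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    stop("'values' needs full dimnames (participants, nodes, waves)", call. = FALSE)
  if (!identical(dn[[2]], scheme$node_ids))
    stop("node dimension must match scheme$node_ids exactly", call. = FALSE)
  if (!is.null(missing_mask))
    stopifnot(identical(dim(missing_mask), dim(values)), is.logical(missing_mask))
  structure(list(values = values,
                 scheme = scheme,
                 participant_ids = dn[[1]],
                 waves = dn[[3]],
                 missing_mask = missing_mask),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("Panel dataset:", length(x$participant_ids), "participants x",
      length(x$scheme$node_ids), "nodes x", length(x$waves), "waves (",
      paste(x$waves, collapse = ", "), ")\n")
  if (!is.null(x$missing_mask))
    cat(sprintf("  missing cells: %d (%.2f%%)\n", sum(x$missing_mask),
                100 * mean(x$missing_mask)))
  invisible(x)
}

#' Extract one wave as a participants x nodes matrix
#'
#' Masked cells are returned as NA.
#' @param panel a \code{panel_dataset}.
#' @param wave wave label.
#' @param nodes optional subset of node ids.
#' @export
wave_matrix <- function(panel, wave, nodes = NULL) {
  stopifnot(inherits(panel, "panel_dataset"))
  if (!wave %in% panel$waves)
    stop("unknown wave '", wave, "'", call. = FALSE)
  m <- panel$values[, , wave, drop = FALSE]
  dim(m) <- dim(panel$values)[1:2]
  dimnames(m) <- dimnames(panel$values)[1:2]
  if (!is.null(panel$missing_mask)) {
    mk <- panel$missing_mask[, , wave]
    m[mk] <- NA_real_
  }
  if (!is.null(nodes)) m <- m[, nodes, drop = FALSE]
  m
}

#' Drop participants with any missing cell
#'
#' The complete-case filter used throughout the pipeline: a participant is
#' retained only if none of their cells (any node, any wave) is missing.
#' @param panel a \code{panel_dataset}.
#' @return A \code{panel_dataset} without a missing mask; the number of
#'   dropped participants is reported via a message.
#' @export
complete_case_filter <- function(panel) {
  stopifnot(inherits(panel, "panel_dataset"))
  if (is.null(panel$missing_mask)) return(panel)
  keep <- apply(panel$missing_mask, 1, function(z) !any(z))
  dropped <- sum(!keep)
  if (dropped) message(dropped, " participant(s) dropped by complete-case filter")
  panel_dataset(panel$values[keep, , , drop = FALSE], panel$scheme)
}

#' Convert a panel dataset to a wide data frame
#'
#' One row per participant, columns \code{<node>_<wave>}; masked cells NA.
#' @param x a \code{panel_dataset}.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.panel_dataset <- function(x, row.names = NULL, optional = FALSE, ...) {
  cols <- list(participant_id = x$participant_ids)
  for (w in x$waves) {
    m <- wave_matrix(x, w)
    for (nd in x$scheme$node_ids) cols[[paste0(nd, "_", w)]] <- m[, nd]
  }
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a panel dataset as wide CSV with a JSON scheme sidecar
#'
#' @param panel a \code{panel_dataset}.
#' @param path CSV output path; the sidecar is written at
#'   \code{paste0(path, ".meta.json")}.
#' @param truth optional list of ground-truth matrices to record in the
#'   sidecar (synthetic data only).
#' @export
write_panel <- function(panel, path, truth = NULL) {
  df <- as.data.frame(panel)
  write.csv(df, path, row.names = FALSE)
  sch <- panel$scheme
  meta <- list(node_ids = sch$node_ids,
               construct = as.character(sch$construct),
               cross_construct_pair = as.character(sch$cross_construct_pair),
               score_bounds = unname(sch$score_bounds),
               items_per_node = unname(sch$items_per_node),
               waves = panel$waves)
  if (!is.null(truth)) meta$truth <- truth
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA)
  invisible(path)
}

#' Load a wide-format panel CSV into a validated panel dataset
#'
#' Expects one row per participant with a \code{participant_id} column and
#' \code{<node>_<wave>} score columns. Values are checked against the
#' scheme's score bounds; rows with any missing analyzed value are dropped
#' (complete-case analysis) with the count reported.
#'
#' @param path CSV path.
#' @param scheme node scheme; defaults to \code{make_node_scheme()}.
#' @param waves wave labels expected in the columns.
#' @return A complete-case \code{panel_dataset}.
#' @export
load_panel <- function(path, scheme = make_node_scheme(),
                       waves = c("T1", "T2", "T3")) {
  validate_scheme(scheme)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"participant_id" %in% names(df))
    stop("input must have a 'participant_id' column", call. = FALSE)
  ids <- as.character(df$participant_id)
  if (anyDuplicated(ids))
    stop("duplicate participant IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  expected <- as.vector(outer(scheme$node_ids, waves, paste, sep = "_"))
  missing_cols <- setdiff(expected, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(head(missing_cols, 5L), collapse = ", "),
         if (length(missing_cols) > 5L) " ...", call. = FALSE)
  extra <- setdiff(names(df), c("participant_id", expected))
  if (length(extra))
    stop("unknown columns: ", paste(extra, collapse = ", "), call. = FALSE)

  vals <- array(NA_real_, dim = c(nrow(df), length(scheme$node_ids), length(waves)),
                dimnames = list(ids, scheme$node_ids, waves))
  for (w in waves) for (nd in scheme$node_ids)
    vals[, nd, w] <- as.numeric(df[[paste0(nd, "_", w)]])

  # bounds check on observed values
  for (nd in scheme$node_ids) {
    b <- scheme$score_bounds[nd, ]
    v <- vals[, nd, ]
    bad <- which(!is.na(v) & (v < b[1] | v > b[2]), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("value out of bounds [%d, %d] for node %s (participant %s, wave %s)",
                   b[1], b[2], nd, ids[bad[1, 1]], waves[bad[1, 2]]), call. = FALSE)
  }

  keep <- apply(vals, 1, function(z) !anyNA(z))
  if (any(!keep))
    message(sum(!keep), " row(s) with missing values dropped (complete-case)")
  panel_dataset(vals[keep, , , drop = FALSE], scheme)
}
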