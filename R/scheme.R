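#' The fixed 27-node layout for IA/distress panel networks
#'
#' Builds the node scheme used throughout the package: the 6 subscales of
#' Young's Internet Addiction Test (IAT; 20 items, each rated 1-5) as
#' internet-addiction (IA) nodes, and the 21 items of the Depression
#' Anxiety Stress Scale (DASS-21; each rated 0-3) as psychological-distress
#' nodes. IA subscale nodes carry the classical 6-factor item allocation
#' (salience 5, excessive use 5, neglect work 3, anticipation 2, lack of
#' control 3, neglect social life 2), so each subscale score is a sum of
#' its items and is bounded by \code{items * c(1, 5)}.
#'
#' For bridge centralities the four constructs collapse to a binary
#' community split: IA versus distress (depression, anxiety and stress
#' together).
#'
#' @return An object of class \code{node_scheme}: a list with
#'   \describe{
#'     \item{node_ids}{character(27): A1-A6, D1-D7, N1-N7, S1-S7.}
#'     \item{construct}{named factor: IA, depression, anxiety or stress.}
#'     \item{cross_construct_pair}{named factor: IA or distress.}
#'     \item{score_bounds}{27 x 2 matrix of integer (min, max) bounds.}
#'     \item{items_per_node}{named integer vector of item counts.}
#'   }
#' @examples
#' sch <- make_node_scheme()
#' sch$score_bounds["A4", ]  # anticipation: 2 items -> bounds (2, 10)
#' @export
make_node_scheme <- function() {
  ia_items <- c(A1 = 5L, A2 = 5L, A3 = 3L, A4 = 2L, A5 = 3L, A6 = 2L)
  dass <- c(paste0("D", 1:7), paste0("N", 1:7), paste0("S", 1:7))
  node_ids <- c(names(ia_items), dass)

  construct <- c(rep("IA", 6L),
                 rep("depression", 7L), rep("anxiety", 7L), rep("stress", 7L))
  names(construct) <- node_ids
  pair <- ifelse(construct == "IA", "IA", "distress")
  names(pair) <- node_ids

  items <- c(ia_items, setNames(rep(1L, 21L), dass))
  bounds <- cbind(min = c(ia_items * 1L, rep(0L, 21L)),
                  max = c(ia_items * 5L, rep(3L, 21L)))
  rownames(bounds) <- node_ids

  structure(list(node_ids = node_ids,
                 construct = factor(construct,
                                    levels = c("IA", "depression", "anxiety", "stress")),
                 cross_construct_pair = factor(pair, levels = c("IA", "distress")),
                 score_bounds = bounds,
                 items_per_node = items),
            class = "node_scheme")
}

#' @export
print.node_scheme <- function(x, ...) {
  cat("Node scheme:", length(x$node_ids), "nodes (",
      sum(x$construct == "IA"), "IA,",
      sum(x$construct != "IA"), "distress )\n")
  cat("  ", paste(x$node_ids, collapse = " "), "\n")
  invisible(x)
}

validate_scheme <- function(scheme) {
  if (!inherits(scheme, "node_scheme"))
    stop("'scheme' must be a node_scheme (see make_node_scheme())", call. = FALSE)
  invisible(scheme)
}

# Community membership vector (IA/distress) in node order.
scheme_communities <- function(scheme) {
  as.character(scheme$cross_construct_pair[scheme$node_ids])
}
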