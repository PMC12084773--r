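# Expected-influence centralities. Undirected: EI1 (signed row sum) and
# EI2 (adds weighted neighbours' EI1). Directed (CLPN): in-/out-expected
# influence over cross-construct paths, and bridge expected influence
# across the IA/distress community boundary.

as_und_weights <- function(network) {
  if (inherits(network, "ggm_network")) network$weights
  else check_symmetric(as.matrix(network))
}

centrality_table <- function(values_list, scope = "all", standardized = FALSE) {
  nodes <- names(values_list[[1]])
  out <- data.frame(node = nodes, stringsAsFactors = FALSE)
  for (nm in names(values_list)) out[[nm]] <- unname(values_list[[nm]])
  attr(out, "scope") <- scope
  attr(out, "standardized") <- standardized
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Z-standardize a centrality table across nodes
#'
#' @param tab a \code{centrality_table} (raw).
#' @export
standardize_centrality <- function(tab) {
  stopifnot(inherits(tab, "centrality_table"))
  for (nm in setdiff(names(tab), "node")) {
    v <- tab[[nm]]
    tab[[nm]] <- if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  }
  attr(tab, "standardized") <- TRUE
  tab
}

#' Expected influence of an undirected network
#'
#' \code{EI1(i) = sum_j w_ij} (signed); \code{EI2(i) = EI1(i) +
#' sum_j w_ij EI1(j)}: the two-step version propagates neighbours'
#' influence through the connecting edge.
#'
#' @param network a \code{ggm_network} or symmetric weights matrix.
#' @param steps 1, 2, or both (default) as \code{c(1, 2)}.
#' @return A \code{centrality_table} with columns EI1 and/or EI2.
#' @export
expected_influence <- function(network, steps = c(1, 2)) {
  w <- as_und_weights(network)
  diag(w) <- 0
  nodes <- rownames(w) %||% paste0("V", seq_len(nrow(w)))
  ei1 <- setNames(rowSums(w), nodes)
  vals <- list()
  if (1 %in% steps) vals$EI1 <- ei1
  if (2 %in% steps) vals$EI2 <- setNames(ei1 + drop(w %*% ei1), nodes)
  centrality_table(vals)
}

clpn_B <- function(network) {
  if (inherits(network, "clpn_network")) network$B_hat
  else check_square(as.matrix(network))
}

resolve_communities <- function(network, communities) {
  if (!is.null(communities)) return(as.character(communities))
  if (inherits(network, "clpn_network") && !is.null(network$scheme))
    return(scheme_communities(network$scheme))
  NULL
}

#' In- and out-expected influence of a directed network
#'
#' OEI(i) sums node i's outgoing cross-lagged coefficients, IEI(j) its
#' incoming ones. With \code{scope = "cross_construct"} (the default)
#' only paths crossing the IA/distress boundary count, isolating the
#' longitudinal interplay between the constructs; \code{scope = "all"}
#' sums every path except the autoregressive diagonal.
#'
#' @param network a \code{clpn_network} or square coefficient matrix.
#' @param scope "cross_construct" or "all".
#' @param communities community label per node; taken from the network's
#'   scheme when available. Required for cross-construct scope.
#' @return A \code{centrality_table} with columns IEI and OEI.
#' @export
in_out_expected_influence <- function(network,
                                      scope = c("cross_construct", "all"),
                                      communities = NULL) {
  scope <- match.arg(scope)
  B <- clpn_B(network)
  nodes <- rownames(B) %||% paste0("V", seq_len(nrow(B)))
  keep <- row(B) != col(B)  # autoregressive always excluded
  if (scope == "cross_construct") {
    comm <- resolve_communities(network, communities)
    if (is.null(comm))
      stop("cross-construct scope needs community labels (scheme or 'communities')",
           call. = FALSE)
    keep <- keep & outer(comm, comm, "!=")
  }
  Bk <- B * keep
  centrality_table(list(IEI = setNames(colSums(Bk), nodes),
                        OEI = setNames(rowSums(Bk), nodes)),
                   scope = scope)
}

#' Bridge expected influence of a directed network
#'
#' BEI1(i) sums the coefficients of node i's edges that cross the
#' IA/distress community boundary, in the selected direction
#' (\code{"out"}: edges i sends, the default; \code{"in"}: edges i
#' receives; \code{"both"}: their sum). The two-step version adds
#' influence transmitted through any intermediate node:
#' \code{BEI2(i) = BEI1(i) + sum_k B[i, k] BEI1(k)}.
#'
#' @param network a \code{clpn_network} or square coefficient matrix.
#' @param steps 1, 2 or both.
#' @param direction "out", "in" or "both".
#' @param communities community label per node (from the scheme when
#'   available).
#' @return A \code{centrality_table} with columns BEI1 and/or BEI2.
#' @export
bridge_expected_influence <- function(network, steps = c(1, 2),
                                      direction = c("out", "in", "both"),
                                      communities = NULL) {
  direction <- match.arg(direction)
  B <- clpn_B(network)
  nodes <- rownames(B) %||% paste0("V", seq_len(nrow(B)))
  comm <- resolve_communities(network, communities)
  if (is.null(comm))
    stop("bridge centrality needs community labels (scheme or 'communities')",
         call. = FALSE)
  cross <- outer(comm, comm, "!=") & row(B) != col(B)
  Bc <- B * cross
  bei1 <- switch(direction,
                 out = rowSums(Bc),
                 `in` = colSums(Bc),
                 both = rowSums(Bc) + colSums(Bc))
  bei1 <- setNames(bei1, nodes)
  vals <- list()
  if (1 %in% steps) vals$BEI1 <- bei1
  if (2 %in% steps) {
    Bnd <- B; diag(Bnd) <- 0
    vals$BEI2 <- setNames(bei1 + drop(Bnd %*% bei1), nodes)
  }
  centrality_table(vals)
}
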