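# Brute-force reference implementations. These deliberately share no code with
# the graph construction or the solver (only count_recombinations, which is
# itself exhaustively specified) so that they can serve as independent ground
# truth in the test suite.

#' Enumeration guards for the brute-force oracles
#'
#' @param max_members,max_sites,max_phase_bits,max_vertices,max_edges integer
#'   limits; enumeration refuses inputs beyond them.
#' @return list of class `oracle_limits`.
#' @export
oracle_limits <- function(max_members = 8L, max_sites = 8L,
                          max_phase_bits = 18L, max_vertices = 20L,
                          max_edges = 40L) {
  structure(list(max_members = as.integer(max_members),
                 max_sites = as.integer(max_sites),
                 max_phase_bits = as.integer(max_phase_bits),
                 max_vertices = as.integer(max_vertices),
                 max_edges = as.integer(max_edges)),
            class = "oracle_limits")
}

#' Exact minimum recombination count by exhaustive phasing
#'
#' Enumerates, for every member, all phase assignments over its heterozygous
#' sites modulo the h1/h2 swap (2^(h-1) per member with h heterozygous sites)
#' and scores each joint assignment with [count_recombinations()].
#'
#' @param ped a [pedigree()].
#' @param limits an [oracle_limits()].
#' @return list with `k` (the minimum) and `witness` (one optimal named list of
#'   [haplotype_pair()]s).
#' @export
brute_force_min_recombination <- function(ped, limits = oracle_limits()) {
  ids <- ped$members$id
  if (length(ids) > limits$max_members) {
    ped_error("oracle_limits_exceeded", "too many members for the oracle")
  }
  if (n_sites(ped) > limits$max_sites) {
    ped_error("oracle_limits_exceeded", "too many sites for the oracle")
  }
  het_sites <- lapply(ids, function(u) which(member_geno(ped, u) == 2L))
  bits <- vapply(het_sites, function(h) max(length(h) - 1L, 0L), 0L)
  if (sum(bits) > limits$max_phase_bits) {
    ped_error("oracle_limits_exceeded",
              "too many heterozygous sites for the oracle (%d bits)", sum(bits))
  }

  # all phasings of one member: first het site anchored to h1 = 0
  member_phasings <- function(u, hets) {
    g <- member_geno(ped, u)
    base <- ifelse(g == 2L, NA_integer_, g)
    h <- length(hets)
    if (h == 0L) return(list(haplotype_pair(base, base)))
    opts <- list()
    for (code in 0:(2^(h - 1L) - 1L)) {
      h1 <- base
      h1[hets[1L]] <- 0L
      if (h > 1L) {
        rest <- as.integer(intToBits(code))[seq_len(h - 1L)]
        h1[hets[-1L]] <- rest
      }
      h2 <- h1
      h2[hets] <- 1L - h1[hets]
      opts[[length(opts) + 1L]] <- haplotype_pair(h1, h2)
    }
    opts
  }
  choices <- lapply(seq_along(ids), function(idx) {
    member_phasings(ids[idx], het_sites[[idx]])
  })
  counts <- vapply(choices, length, 0L)
  idxs <- rep(1L, length(ids))
  best_k <- Inf
  best_w <- NULL
  repeat {
    phases <- stats::setNames(
      lapply(seq_along(ids), function(i) choices[[i]][[idxs[i]]]), ids)
    # configurations where some child haplotype is not producible from a
    # parent at all (single-site impossibility) are skipped, not errors
    res <- tryCatch(count_recombinations(ped, phases),
                    pedphase_error = function(e) NULL)
    if (!is.null(res) && res$k < best_k) {
      best_k <- res$k
      best_w <- phases
      if (best_k == 0L) break
    }
    # odometer increment
    pos <- 1L
    while (pos <= length(ids)) {
      idxs[pos] <- idxs[pos] + 1L
      if (idxs[pos] <= counts[pos]) break
      idxs[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > length(ids)) break
  }
  list(k = as.integer(best_k), witness = best_w)
}

#' Exact minimum edge bipartization by exhaustive 2-coloring
#'
#' Minimum over all 2-colorings of the number of monochromatic edges,
#' optionally restricted to colorings with an even red count in every parity
#' set and/or with some vertices pinned to a side.
#'
#' @param edges data.frame/matrix with columns `v1`, `v2` (vertex ids, any
#'   atomic type); parallel edges count separately.
#' @param vertices optional vector of all vertex ids (defaults to those in
#'   `edges` plus those in `parity_sets` and `fixed`).
#' @param parity_sets optional list of lists with fields `vids` (vertex ids)
#'   and `offset` (constant red count added to the set); a coloring is
#'   admissible when `offset + #red(vids)` is even for every set. Side "A" is
#'   red.
#' @param fixed optional named vector of sides ("A"/"B") pinning vertices.
#' @param limits an [oracle_limits()].
#' @return list with `k` (minimum removals, `Inf` if no admissible coloring)
#'   and `coloring` (one optimal named side vector).
#' @export
brute_force_bipartization <- function(edges, vertices = NULL,
                                      parity_sets = list(), fixed = NULL,
                                      limits = oracle_limits()) {
  edges <- as.data.frame(edges)
  vids <- unique(as.character(c(as.vector(edges$v1), as.vector(edges$v2),
                                unlist(lapply(parity_sets, `[[`, "vids")),
                                names(fixed), vertices)))
  vids <- vids[!is.na(vids)]
  if (length(vids) > limits$max_vertices) {
    ped_error("oracle_limits_exceeded", "too many vertices for the oracle")
  }
  if (nrow(edges) > limits$max_edges) {
    ped_error("oracle_limits_exceeded", "too many edges for the oracle")
  }
  free <- setdiff(vids, names(fixed))
  best_k <- Inf
  best_col <- NULL
  nfree <- length(free)
  for (code in 0:(2^nfree - 1L)) {
    side <- stats::setNames(rep("B", length(vids)), vids)
    if (!is.null(fixed)) side[names(fixed)] <- fixed
    if (nfree > 0L) {
      bits <- as.integer(intToBits(code))[seq_len(nfree)]
      side[free[bits == 1L]] <- "A"
    }
    ok <- TRUE
    for (ps in parity_sets) {
      nred <- ps$offset + sum(side[as.character(ps$vids)] == "A")
      if (nred %% 2L != 0L) { ok <- FALSE; break }
    }
    if (!ok) next
    mono <- sum(side[as.character(edges$v1)] == side[as.character(edges$v2)])
    if (mono < best_k) {
      best_k <- mono
      best_col <- side
    }
  }
  list(k = best_k, coloring = best_col)
}

#' Enumerate all s-t minimum cuts by exhaustive bipartition
#'
#' Evaluates every source-side subset S (s in S, t not in S); a cut's value is
#' the total capacity of arcs leaving S. Returns every cut achieving the
#' minimum.
#'
#' @param net a flow network from [make_flow_network()] (flows are ignored;
#'   only arcs/capacities are used).
#' @param limits an [oracle_limits()].
#' @return list with `value` (the minimum cut value) and `cuts`: a list, one
#'   entry per mincut, each a list with `S` (sorted source-side node ids) and
#'   `edges` (sorted undirected edge ids crossing the cut; `NA` entries from
#'   super-terminal arcs never occur in finite cuts).
#' @export
enumerate_all_mincuts <- function(net, limits = oracle_limits()) {
  nodes <- setdiff(seq_len(net$n_nodes), c(net$s, net$t))
  if (length(nodes) > limits$max_vertices) {
    ped_error("oracle_limits_exceeded", "too many nodes for the oracle")
  }
  arcs <- net$arcs
  fwd <- arcs$cap > 0L
  best <- Inf
  cuts <- list()
  nn <- length(nodes)
  for (code in 0:(2^nn - 1L)) {
    inS <- c(net$s, nodes[as.logical(as.integer(intToBits(code))[seq_len(nn)])])
    sideS <- rep(FALSE, net$n_nodes)
    sideS[inS] <- TRUE
    cross <- fwd & sideS[arcs$from] & !sideS[arcs$to]
    val <- sum(arcs$cap[cross])
    if (val < best) {
      best <- val
      cuts <- list()
    }
    if (val == best && is.finite(val)) {
      cuts[[length(cuts) + 1L]] <- list(
        S = sort(inS),
        edges = sort(unique(arcs$edge_id[cross & !is.na(arcs$edge_id)])))
    }
  }
  list(value = best, cuts = cuts)
}
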