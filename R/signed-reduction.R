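# Signed-graph line index and the chain of transformations that turns the
# pedigree graph into an all-positive multigraph for bipartization by edge
# removal: positive edges are split into two negative edges through a fresh
# "dum" vertex (which preserves the line index), edges between two already
# resolved vertices are folded into a constant, all red vertices are merged
# into one anchor and all green vertices into another (joined by budget+1
# parallel edges so no feasible solution may put them on one side), and
# finally every weight is negated.

# normalize the various graph shapes to a common signed edge list;
# aux_group marks mediator vertices (delivery vertices grouped per trio, dum
# vertices singly) that the brute force may minimize out locally
as_signed <- function(g) {
  if (inherits(g, "pedigree_graph")) {
    v <- g$vertices
    keep <- !v$pruned
    live <- v$vid[keep]
    aux <- ifelse(v$origin[keep] == "delivery",
                  paste0("E:", v$member[keep]), NA_character_)
    list(edges = data.frame(v1 = g$edges$v1, v2 = g$edges$v2,
                            sign = g$edges$sign),
         vertex_ids = live,
         colors = stats::setNames(v$color[keep], live),
         aux_group = stats::setNames(aux, live),
         parity_sets = g$parity_sets)
  } else if (inherits(g, "signed_graph")) {
    ids <- seq_len(g$n_vertices)
    list(edges = g$edges[, c("v1", "v2", "sign")], vertex_ids = ids,
         colors = stats::setNames(rep("grey", length(ids)), ids),
         aux_group = stats::setNames(rep(NA_character_, length(ids)), ids),
         parity_sets = list())
  } else if (inherits(g, "signed_transform")) {
    ids <- g$vertices$tvid
    aux <- ifelse(g$vertices$kind == "dum", paste0("dum:", ids),
                  NA_character_)
    list(edges = data.frame(v1 = g$edges$v1, v2 = g$edges$v2,
                            sign = ifelse(g$edges$weight < 0, -1L, 1L)),
         vertex_ids = ids,
         colors = stats::setNames(g$vertices$color, ids),
         aux_group = stats::setNames(aux, ids),
         parity_sets = g$parity_sets)
  } else {
    stop("unsupported graph object")
  }
}

#' Line index of a vertex bipartition
#'
#' The number of positive edges whose endpoints lie in different parts plus
#' the number of negative edges whose endpoints lie in the same part: the
#' count of violated transmission constraints, i.e. of recombination events.
#'
#' @param g a `pedigree_graph`, `signed_graph`, or `signed_transform`.
#' @param part named vector (names = vertex ids) with two levels, e.g.
#'   `"V1"`/`"V2"`; must cover every vertex of `g`.
#' @return integer.
#' @export
line_index_of_partition <- function(g, part) {
  sg <- as_signed(g)
  miss <- setdiff(as.character(sg$vertex_ids), names(part))
  if (length(miss)) {
    ped_error("partial_partition", "partition misses vertex %s", miss[1L])
  }
  e <- sg$edges
  same <- part[as.character(e$v1)] == part[as.character(e$v2)]
  sum(e$sign == 1L & !same) + sum(e$sign == -1L & same)
}

#' Brute-force line index
#'
#' Minimum of [line_index_of_partition()] over all bipartitions, one side
#' fixed by symmetry. Optionally respects resolved vertex colors (red and
#' green vertices pinned to opposite parts) and parity-constraint sets (even
#' red count per set, counting phantom chain vertices as free variables).
#'
#' @param g graph as in [line_index_of_partition()].
#' @param respect_colors pin resolved vertices to their color's part.
#' @param parity enforce `g`'s parity-constraint sets.
#' @param limits an [oracle_limits()]; enumeration guard.
#' @details Mediator vertices (delivery vertices, grouped per trio, and dum
#'   vertices) interact with the rest of the graph only through their own
#'   edges and parity sets and are independent across groups, so for each
#'   assignment of the main vertices every mediator group is minimized out
#'   exactly by local enumeration; the guard applies to the main vertices.
#' @return integer minimum (`Inf` when no admissible partition exists).
#' @export
brute_force_line_index <- function(g, respect_colors = FALSE, parity = FALSE,
                                   limits = oracle_limits()) {
  sg <- as_signed(g)
  psets <- if (parity) sg$parity_sets else list()
  all_ids <- as.character(
    unique(c(sg$vertex_ids, unlist(lapply(psets, `[[`, "vids")))))
  aux_of <- sg$aux_group[all_ids]
  pinned <- character(0)
  if (respect_colors) {
    res <- names(sg$colors)[sg$colors %in% c("red", "green")]
    pinned <- stats::setNames(
      ifelse(sg$colors[res] == "red", "V1", "V2"), res)
  }
  free <- setdiff(all_ids, names(pinned))
  free_aux <- free[!is.na(aux_of[free])]
  free_main <- setdiff(free, free_aux)
  if (length(free_main) > limits$max_vertices || length(free_aux) > 60L) {
    ped_error("oracle_limits_exceeded",
              "too many free vertices (%d main, %d mediator) for brute-force line index",
              length(free_main), length(free_aux))
  }
  groups <- split(free_aux, aux_of[free_aux])
  if (any(lengths(groups) > 12L)) {
    ped_error("oracle_limits_exceeded", "mediator group too large")
  }
  e <- sg$edges
  v1c <- as.character(e$v1); v2c <- as.character(e$v2)
  edge_aux <- ifelse(!is.na(aux_of[v1c]), aux_of[v1c], aux_of[v2c])
  # parity sets touching a mediator group are resolved within that group;
  # each set may touch at most one group by construction
  pset_group <- vapply(psets, function(ps) {
    gs <- unique(stats::na.omit(aux_of[as.character(ps$vids)]))
    if (length(gs) > 1L) {
      ped_error("graph_internal", "parity set spans mediator groups")
    }
    if (length(gs)) gs else NA_character_
  }, "")
  best <- Inf
  n_main <- length(free_main)
  for (code in 0:(max(2^n_main - 1L, 0L))) {
    side <- stats::setNames(rep("V2", length(all_ids)), all_ids)
    side[names(pinned)] <- pinned
    if (n_main) {
      bits <- as.integer(intToBits(code))[seq_len(n_main)]
      side[free_main[bits == 1L]] <- "V1"
    }
    ok <- TRUE
    for (si in seq_along(psets)) {
      if (!is.na(pset_group[si])) next
      ps <- psets[[si]]
      off <- if (is.null(ps$offset)) 0L else ps$offset
      if ((off + sum(side[as.character(ps$vids)] == "V1")) %% 2L != 0L) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    base_idx <- is.na(edge_aux)
    same <- side[v1c[base_idx]] == side[v2c[base_idx]]
    li <- sum(e$sign[base_idx] == 1L & !same) +
      sum(e$sign[base_idx] == -1L & same)
    for (gname in names(groups)) {
      gv <- groups[[gname]]
      g_edges <- which(!is.na(edge_aux) & edge_aux == gname)
      g_sets <- which(!is.na(pset_group) & pset_group == gname)
      gbest <- Inf
      for (gc in 0:(2^length(gv) - 1L)) {
        gb <- as.integer(intToBits(gc))[seq_along(gv)]
        side[gv] <- ifelse(gb == 1L, "V1", "V2")
        gok <- TRUE
        for (si in g_sets) {
          ps <- psets[[si]]
          off <- if (is.null(ps$offset)) 0L else ps$offset
          if ((off + sum(side[as.character(ps$vids)] == "V1")) %% 2L != 0L) {
            gok <- FALSE; break
          }
        }
        if (!gok) next
        same_g <- side[v1c[g_edges]] == side[v2c[g_edges]]
        gcost <- sum(e$sign[g_edges] == 1L & !same_g) +
          sum(e$sign[g_edges] == -1L & same_g)
        gbest <- min(gbest, gcost)
        if (gbest == 0) break
      }
      li <- li + gbest
      if (li >= best) break
    }
    best <- min(best, li)
    if (best == 0) break
  }
  best
}

#' Replace positive edges by negative two-edge paths
#'
#' Every positive edge (u, v) becomes edges (u, y), (y, v) of weight -1
#' through a fresh intermediate "dum" vertex y belonging to no member and no
#' parity set; the line index is unchanged. Negative edges are kept.
#'
#' @param g a `pedigree_graph` or `signed_graph`.
#' @return object of class `signed_transform` with all-negative `edges`
#'   (columns v1/v2/weight/origin_eid/role), a `vertices` table (tvid/kind/
#'   color/member/orig_vid), `baseline_cost`, `parity_sets`, and `anchors`
#'   (filled in by [merge_resolved()]).
#' @export
positive_to_negative <- function(g) {
  sg <- as_signed(g)
  if (inherits(g, "pedigree_graph")) {
    vtab <- g$vertices
    next_id <- max(vtab$vid, 0L) + 1L
    keep <- !vtab$pruned
    verts <- data.frame(tvid = vtab$vid[keep],
                        kind = rep("orig", sum(keep)),
                        color = vtab$color[keep],
                        member = vtab$member[keep],
                        orig_vid = vtab$vid[keep],
                        stringsAsFactors = FALSE)
  } else {
    verts <- data.frame(tvid = sg$vertex_ids,
                        kind = rep("orig", length(sg$vertex_ids)),
                        color = unname(sg$colors),
                        member = rep(NA_character_, length(sg$vertex_ids)),
                        orig_vid = sg$vertex_ids, stringsAsFactors = FALSE)
    next_id <- max(sg$vertex_ids, 0L) + 1L
  }
  eid <- if (inherits(g, "pedigree_graph")) g$edges$eid else
    seq_len(nrow(sg$edges))
  v1 <- integer(0); v2 <- integer(0); origin <- integer(0); role <- character(0)
  for (r in seq_len(nrow(sg$edges))) {
    a <- sg$edges$v1[r]; b <- sg$edges$v2[r]
    if (sg$edges$sign[r] == -1L) {
      v1 <- c(v1, a); v2 <- c(v2, b); origin <- c(origin, eid[r])
      role <- c(role, "orig")
    } else {
      y <- next_id; next_id <- next_id + 1L
      verts <- rbind(verts, data.frame(tvid = y, kind = "dum", color = "grey",
                                       member = NA_character_, orig_vid = NA,
                                       stringsAsFactors = FALSE))
      v1 <- c(v1, a, y); v2 <- c(v2, y, b)
      origin <- c(origin, eid[r], eid[r])
      role <- c(role, "dumhalf", "dumhalf")
    }
  }
  structure(list(
    vertices = verts,
    edges = data.frame(v1 = v1, v2 = v2, weight = rep(-1L, length(v1)),
                       origin_eid = origin, role = role,
                       stringsAsFactors = FALSE),
    baseline_cost = 0L, baseline_eids = integer(0),
    budget = NA_integer_, anchors = NULL,
    parity_sets = sg$parity_sets, orig = g), class = "signed_transform")
}

#' Fold partition-independent edge costs into a constant
#'
#' A negative edge joining two resolved vertices contributes the same cost to
#' every partition: nothing when the colors differ, one forced recombination
#' when they agree. Such edges are removed before merging (merging equal
#' colors would otherwise create self-loops) and the forced cost is kept in
#' `baseline_cost` with the edge recorded for event localization.
#'
#' @param tg a `signed_transform` (all edges negative).
#' @return updated `signed_transform`.
#' @export
fold_constant_costs <- function(tg) {
  stopifnot(inherits(tg, "signed_transform"))
  col <- stats::setNames(tg$vertices$color, tg$vertices$tvid)
  drop <- logical(nrow(tg$edges))
  for (r in seq_len(nrow(tg$edges))) {
    if (tg$edges$role[r] != "orig") next
    c1 <- col[[as.character(tg$edges$v1[r])]]
    c2 <- col[[as.character(tg$edges$v2[r])]]
    if (c1 != "grey" && c2 != "grey") {
      drop[r] <- TRUE
      if (c1 == c2) {
        tg$baseline_cost <- tg$baseline_cost + 1L
        tg$baseline_eids <- c(tg$baseline_eids, tg$edges$origin_eid[r])
      }
    }
  }
  tg$edges <- tg$edges[!drop, , drop = FALSE]
  rownames(tg$edges) <- NULL
  tg
}

#' Merge resolved vertices into two anchors
#'
#' All red vertices are identified into one anchor and all green vertices into
#' another; both anchors are relabeled grey and joined by `budget + 1`
#' parallel negative edges, so any solution within budget must separate them
#' (the anchor side then defines which part is "red"). Parity sets keep their
#' grey members; merged-away resolved vertices become a constant red-count
#' offset.
#'
#' @param tg a `signed_transform` after [fold_constant_costs()].
#' @param k the decision budget for the current instance.
#' @return updated `signed_transform` with `anchors`, `budget`
#'   (`k - baseline_cost`) and rewritten `parity_sets` (fields `member`,
#'   `vids`, `offset`).
#' @export
merge_resolved <- function(tg, k) {
  stopifnot(inherits(tg, "signed_transform"))
  budget <- as.integer(k) - tg$baseline_cost
  next_id <- max(tg$vertices$tvid, 0L) + 1L
  red_anchor <- next_id; green_anchor <- next_id + 1L
  col <- stats::setNames(tg$vertices$color, tg$vertices$tvid)
  remap <- function(v) {
    cc <- col[[as.character(v)]]
    if (cc == "red") red_anchor else if (cc == "green") green_anchor else v
  }
  if (nrow(tg$edges)) {
    tg$edges$v1 <- vapply(tg$edges$v1, remap, 0L)
    tg$edges$v2 <- vapply(tg$edges$v2, remap, 0L)
    if (any(tg$edges$v1 == tg$edges$v2)) {
      ped_error("graph_internal",
                "merge produced a self-loop; constant costs were not folded")
    }
  }
  keep <- col == "grey"
  tg$vertices <- rbind(
    tg$vertices[keep[as.character(tg$vertices$tvid)], , drop = FALSE],
    data.frame(tvid = c(red_anchor, green_anchor), kind = "anchor",
               color = "grey", member = NA_character_, orig_vid = NA,
               stringsAsFactors = FALSE))
  n_gadget <- max(budget + 1L, 1L)
  tg$edges <- rbind(tg$edges, data.frame(
    v1 = rep(red_anchor, n_gadget), v2 = rep(green_anchor, n_gadget),
    weight = -1L, origin_eid = NA_integer_, role = "anchor",
    stringsAsFactors = FALSE))
  tg$parity_sets <- lapply(tg$parity_sets, function(ps) {
    cc <- col[as.character(ps$vids)]
    cc[is.na(cc)] <- "grey"                     # phantom (pruned) chain vertex
    base <- if (is.null(ps$offset)) 0L else ps$offset
    list(member = ps$member, vids = ps$vids[cc == "grey"],
         offset = (base + sum(cc == "red")) %% 2L)
  })
  tg$anchors <- c(red = red_anchor, green = green_anchor)
  tg$budget <- budget
  tg
}

#' Negate weights: the bipartization-by-edge-removal instance
#'
#' After negation every edge has weight +1 and the task is to delete at most
#' `budget` edges so that the remaining multigraph is bipartite, subject to
#' the parity sets. Provenance is preserved edge by edge.
#'
#' @param tg a `signed_transform` after [merge_resolved()].
#' @return object of class `gber_instance`: `edges` (v1/v2/origin_eid/role in
#'   the deterministic solver order: anchor gadget edges first), `vertices`,
#'   `budget`, `anchors`, `parity_sets`, `baseline_cost`, `baseline_eids`.
#' @export
to_gber_instance <- function(tg) {
  stopifnot(inherits(tg, "signed_transform"), !is.null(tg$anchors))
  e <- tg$edges
  ord <- order(e$role != "anchor", e$origin_eid, e$v1, e$v2)
  e <- e[ord, c("v1", "v2", "origin_eid", "role")]
  rownames(e) <- NULL
  structure(list(edges = e, vertices = tg$vertices, budget = tg$budget,
                 anchors = tg$anchors, parity_sets = tg$parity_sets,
                 baseline_cost = tg$baseline_cost,
                 baseline_eids = tg$baseline_eids,
                 orig = tg$orig), class = "gber_instance")
}

#' Serialize a GBER instance to an edge-list text format
#'
#' One line per edge: `v1 v2 origin role`; lines starting with `#` carry the
#' budget, anchors and parity sets. For debugging and for feeding oracles.
#'
#' @param inst a `gber_instance`.
#' @param file optional path.
#' @return character lines, invisibly when written.
#' @export
gber_to_text <- function(inst, file = NULL) {
  head <- c(sprintf("# budget %d baseline %d", inst$budget,
                    inst$baseline_cost),
            sprintf("# anchors red=%d green=%d", inst$anchors[["red"]],
                    inst$anchors[["green"]]),
            vapply(inst$parity_sets, function(ps) {
              sprintf("# parity %s offset=%d vids=%s", ps$member, ps$offset,
                      paste(ps$vids, collapse = ","))
            }, ""))
  body <- vapply(seq_len(nrow(inst$edges)), function(r) {
    e <- inst$edges[r, ]
    sprintf("%d %d %s %s", e$v1, e$v2,
            ifelse(is.na(e$origin_eid), ".", as.character(e$origin_eid)),
            e$role)
  }, "")
  lines <- c(head, body)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Build the GBER instance for a pedigree graph and budget k
#'
#' Convenience composition of [positive_to_negative()],
#' [fold_constant_costs()], [merge_resolved()] and [to_gber_instance()].
#'
#' @param pg a `pedigree_graph`.
#' @param k decision budget (total recombination events).
#' @return a `gber_instance` (its `budget` is `k - baseline_cost`; negative
#'   budget means this `k` is infeasible outright).
#' @export
pedigree_gber_instance <- function(pg, k) {
  to_gber_instance(merge_resolved(fold_constant_costs(positive_to_negative(pg)), k))
}
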