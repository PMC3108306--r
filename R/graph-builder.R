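# Colored signed pedigree graph construction.
#
# Vertices and their meaning:
#   * primary_het  u_ij : phase pattern of member u over consecutive
#     heterozygous sites (i, j); grey until resolved. Green = h1 carries equal
#     alleles at i and j, red = h1 flips.
#   * primary_hom  u_ij : consecutive homozygous pair; resolved red when the
#     genotype codes differ, green when they agree.
#   * supplementary u_ij: phase pattern over a non-consecutive heterozygous
#     pair, created when a transmission constraint needs it; tied to the
#     member's chain by a parity-constraint set.
#   * delivery (E) vertices: one per (child, site) where the child and both
#     parents are heterozygous — the allele the father transmits there (the
#     mother's is its complement). Free mediators belonging to no member.
#   * const (K) vertices: resolved constants materializing transmitted
#     patterns that are fully pinned.
#
# Cost model: the minimum number of source switches in the transmission from
# parent p to child c equals the number of consecutive-heterozygous pairs
# (a, b) of p whose delivered flip differs from p's phase flip. The delivered
# allele at a site is pinned by a homozygous child (g_c) or a homozygous
# co-parent, otherwise it is a free delivery variable. Each pair cost is then
# a single signed edge: positive = endpoints should agree, negative =
# disagree, weight-1 violation = one recombination event. Hard relations
# (child chain flip = XOR of the two deliveries at its endpoints) are pinned
# colors or parity-constraint sets with a constant offset, never costs.

gb_new <- function(ped) {
  gb <- new.env(parent = emptyenv())
  gb$ped <- ped
  gb$member <- character(0); gb$i <- integer(0); gb$j <- integer(0)
  gb$color <- character(0); gb$origin <- character(0)
  gb$forced <- logical(0); gb$pruned <- logical(0)
  gb$deg <- integer(0)
  gb$vkey <- new.env(parent = emptyenv())
  gb$ev1 <- integer(0); gb$ev2 <- integer(0); gb$esign <- integer(0)
  gb$etrio <- character(0); gb$epmember <- character(0)
  gb$ekey <- new.env(parent = emptyenv())
  gb$psets <- list()
  gb$pskey <- new.env(parent = emptyenv())
  gb$log <- character(0)
  gb
}

gb_vkey <- function(member, i, j) paste(member, i, j, sep = "|")

gb_get <- function(gb, key) {
  if (exists(key, envir = gb$vkey, inherits = FALSE)) {
    get(key, envir = gb$vkey, inherits = FALSE)
  } else {
    NA_integer_
  }
}

gb_lookup <- function(gb, member, i, j) gb_get(gb, gb_vkey(member, i, j))

gb_add_vertex <- function(gb, member, i, j, color, origin, key = NULL) {
  vid <- length(gb$member) + 1L
  gb$member[vid] <- member; gb$i[vid] <- i; gb$j[vid] <- j
  gb$color[vid] <- color; gb$origin[vid] <- origin
  gb$forced[vid] <- FALSE; gb$pruned[vid] <- FALSE; gb$deg[vid] <- 0L
  if (is.null(key)) key <- gb_vkey(member, i, j)
  assign(key, vid, envir = gb$vkey)
  vid
}

pair_color <- function(g, i, j) {
  if (g[i] == 2L && g[j] == 2L) return("grey")
  if (g[i] != 2L && g[j] != 2L) return(if (g[i] != g[j]) "red" else "green")
  NA_character_
}

both_het <- function(g, i, j) g[i] == 2L && g[j] == 2L
both_hom <- function(g, i, j) g[i] != 2L && g[j] != 2L
one_het <- function(g, i, j) xor(g[i] == 2L, g[j] == 2L)

# signed edge, deduplicated; v1 is always the parent-side pattern vertex so
# that event localization can read the interval and parent from it
gb_add_edge <- function(gb, v1, v2, sign, trio_child, parent_member) {
  k <- paste(v1, v2, sign, trio_child, sep = "|")
  if (exists(k, envir = gb$ekey, inherits = FALSE)) return(FALSE)
  assign(k, TRUE, envir = gb$ekey)
  e <- length(gb$ev1) + 1L
  gb$ev1[e] <- v1; gb$ev2[e] <- v2; gb$esign[e] <- sign
  gb$etrio[e] <- trio_child; gb$epmember[e] <- parent_member
  gb$deg[v1] <- gb$deg[v1] + 1L; gb$deg[v2] <- gb$deg[v2] + 1L
  TRUE
}

gb_add_pset <- function(gb, member, vids, offset, kind) {
  k <- paste(kind, member, paste(sort(vids), collapse = ","), offset %% 2L,
             sep = "|")
  if (exists(k, envir = gb$pskey, inherits = FALSE)) return(FALSE)
  assign(k, TRUE, envir = gb$pskey)
  gb$psets[[length(gb$psets) + 1L]] <-
    list(member = member, vids = vids, offset = offset %% 2L, kind = kind)
  TRUE
}

gb_pin <- function(gb, vid, color, why) {
  if (gb$color[vid] == "grey") {
    gb$color[vid] <- color
    gb$forced[vid] <- TRUE
    return(TRUE)
  }
  if (gb$color[vid] != color) {
    key <- sprintf("pin conflict at %s(%d,%d): %s", gb$member[vid],
                   gb$i[vid], gb$j[vid], why)
    if (!key %in% gb$log) gb$log[length(gb$log) + 1L] <- key
  }
  FALSE
}

#' Site-pair vertices of a single member
#'
#' One grey vertex per pair of consecutive heterozygous sites and one resolved
#' vertex per pair of consecutive homozygous sites (red when the two genotype
#' codes differ, green when they agree).
#'
#' @param geno genotype vector over `{0,1,2}`.
#' @return data.frame with columns `i`, `j`, `color`, `origin`, ordered by
#'   `(i, j)`.
#' @export
build_member_vertices <- function(geno) {
  geno <- as.integer(geno)
  rows <- list()
  het <- which(geno == 2L)
  hom <- which(geno != 2L)
  if (length(het) >= 2L) {
    for (a in seq_len(length(het) - 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        i = het[a], j = het[a + 1L], color = "grey", origin = "primary_het",
        stringsAsFactors = FALSE)
    }
  }
  if (length(hom) >= 2L) {
    for (a in seq_len(length(hom) - 1L)) {
      i <- hom[a]; j <- hom[a + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j, color = if (geno[i] != geno[j]) "red" else "green",
        origin = "primary_hom", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(i = integer(0), j = integer(0), color = character(0),
               origin = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

gb_init_primary <- function(gb) {
  ped <- gb$ped
  for (u in ped$members$id) {
    vt <- build_member_vertices(member_geno(ped, u))
    for (r in seq_len(nrow(vt))) {
      gb_add_vertex(gb, u, vt$i[r], vt$j[r], vt$color[r], vt$origin[r])
    }
  }
  invisible(gb)
}

# phase-pattern vertex of member u over heterozygous pair (i, j), creating a
# supplementary vertex (plus its chain parity set) when the pair is
# non-consecutive
gb_pattern_vertex <- function(gb, u, i, j) {
  vid <- gb_lookup(gb, u, i, j)
  if (!is.na(vid)) return(vid)
  gu <- member_geno(gb$ped, u)
  stopifnot(both_het(gu, i, j))
  vid <- gb_add_vertex(gb, u, i, j, "grey", "supplementary")
  chain_sites <- which(gu == 2L)
  chain_sites <- chain_sites[chain_sites >= i & chain_sites <= j]
  chain <- integer(0)
  for (a in seq_len(length(chain_sites) - 1L)) {
    cv <- gb_lookup(gb, u, chain_sites[a], chain_sites[a + 1L])
    if (is.na(cv)) {
      ped_error("graph_internal",
                "parity chain of %s(%d,%d) misses primary vertex (%d,%d)",
                u, i, j, chain_sites[a], chain_sites[a + 1L])
    }
    chain <- c(chain, cv)
  }
  gb_add_pset(gb, u, c(vid, chain), 0L, "chain")
  vid
}

gb_delivery_vertex <- function(gb, child, s) {
  key <- paste("E", gb_vkey(child, s, s))
  vid <- gb_get(gb, key)
  if (is.na(vid)) {
    vid <- gb_add_vertex(gb, child, s, s, "grey", "delivery", key = key)
  }
  vid
}

gb_const_vertex <- function(gb, child, color) {
  key <- paste("K", gb_vkey(child, 0L, 0L), color)
  vid <- gb_get(gb, key)
  if (is.na(vid)) {
    vid <- gb_add_vertex(gb, child, 0L, 0L, color, "const", key = key)
    gb$forced[vid] <- TRUE
  }
  vid
}

# per-site delivery status for one trio, father-side convention:
# value = allele the father transmits. type: "chom" (child homozygous),
# "pinned" (child het, some parent homozygous), "free" (all three het).
gb_delivery_status <- function(gb, father, mother, child) {
  gfa <- member_geno(gb$ped, father)
  gmo <- member_geno(gb$ped, mother)
  gc <- member_geno(gb$ped, child)
  m <- length(gc)
  type <- character(m); value <- rep(NA_integer_, m)
  for (s in seq_len(m)) {
    if (gc[s] != 2L) {
      type[s] <- "chom"; value[s] <- gc[s]
    } else if (gfa[s] != 2L) {
      type[s] <- "pinned"; value[s] <- gfa[s]
      if (gmo[s] != 2L && 1L - gmo[s] != gfa[s]) {
        gb$log[length(gb$log) + 1L] <-
          sprintf("Mendelian conflict at %s site %d", child, s)
      }
    } else if (gmo[s] != 2L) {
      type[s] <- "pinned"; value[s] <- 1L - gmo[s]
    } else {
      type[s] <- "free"
    }
  }
  list(type = type, value = value)
}

# all transmission constraints contributed by one trio; idempotent
gb_trio_constraints <- function(gb, father, mother, child) {
  changed <- FALSE
  ds <- gb_delivery_status(gb, father, mother, child)
  gc <- member_geno(gb$ped, child)

  # hard chain relations: for each consecutive child-het pair (x, y) the
  # phase flip equals d_x XOR d_y
  chets <- which(gc == 2L)
  if (length(chets) >= 2L) {
    for (a in seq_len(length(chets) - 1L)) {
      x <- chets[a]; y <- chets[a + 1L]
      cvid <- gb_lookup(gb, child, x, y)
      tx <- ds$type[x]; ty <- ds$type[y]
      if (tx == "pinned" && ty == "pinned") {
        want <- if (ds$value[x] != ds$value[y]) "red" else "green"
        changed <- gb_pin(gb, cvid, want, "pinned deliveries") || changed
      } else if (tx == "pinned" || ty == "pinned") {
        sfree <- if (tx == "free") x else y
        k <- ds$value[if (tx == "pinned") x else y]
        evid <- gb_delivery_vertex(gb, child, sfree)
        changed <- gb_add_pset(gb, child, c(cvid, evid), k, "link") || changed
      } else {
        ex <- gb_delivery_vertex(gb, child, x)
        ey <- gb_delivery_vertex(gb, child, y)
        changed <- gb_add_pset(gb, child, c(cvid, ex, ey), 0L, "link") ||
          changed
      }
    }
  }

  # cost edges: one per consecutive-het pair of each parent
  for (p in c(father, mother)) {
    is_mother <- identical(p, mother)
    gp <- member_geno(gb$ped, p)
    phets <- which(gp == 2L)
    if (length(phets) < 2L) next
    for (a in seq_len(length(phets) - 1L)) {
      i <- phets[a]; j <- phets[a + 1L]
      pvid <- gb_lookup(gb, p, i, j)
      # endpoint expressions: constant part and free delivery sites
      const <- 0L
      free_sites <- integer(0)
      for (s in c(i, j)) {
        if (ds$type[s] == "free") {
          free_sites <- c(free_sites, s)
          if (is_mother) const <- const + 1L     # mother delivers complement
        } else {
          v <- ds$value[s]
          if (is_mother && ds$type[s] == "pinned") v <- 1L - v
          const <- const + v
        }
      }
      const <- const %% 2L
      if (length(free_sites) == 0L) {
        kv <- gb_const_vertex(gb, child, if (const == 1L) "red" else "green")
        changed <- gb_add_edge(gb, pvid, kv, 1L, child, p) || changed
      } else if (length(free_sites) == 1L) {
        evid <- gb_delivery_vertex(gb, child, free_sites)
        sign <- if (const == 0L) 1L else -1L
        changed <- gb_add_edge(gb, pvid, evid, sign, child, p) || changed
      } else {
        cvid <- gb_pattern_vertex(gb, child, i, j)
        sign <- if (const == 0L) 1L else -1L
        changed <- gb_add_edge(gb, pvid, cvid, sign, child, p) || changed
      }
    }
  }
  changed
}

gb_prune_isolated <- function(gb) {
  in_pset <- unique(unlist(lapply(gb$psets, `[[`, "vids")))
  changed <- FALSE
  for (vid in seq_along(gb$member)) {
    if (gb$pruned[vid] || gb$color[vid] != "grey") next
    if (gb$deg[vid] == 0L && !(vid %in% in_pset)) {
      gb$pruned[vid] <- TRUE
      changed <- TRUE
      gb$log[length(gb$log) + 1L] <- sprintf(
        "vertex %s(%d,%d) pruned: no incident edge and no parity constraint",
        gb$member[vid], gb$i[vid], gb$j[vid])
    }
  }
  changed
}

gb_finalize <- function(gb) {
  v <- data.frame(vid = seq_along(gb$member), member = gb$member,
                  i = gb$i, j = gb$j, color = gb$color, origin = gb$origin,
                  forced = gb$forced, pruned = gb$pruned,
                  stringsAsFactors = FALSE)
  e <- data.frame(eid = seq_along(gb$ev1), v1 = gb$ev1, v2 = gb$ev2,
                  sign = gb$esign, trio = gb$etrio, pmember = gb$epmember,
                  stringsAsFactors = FALSE)
  structure(list(vertices = v, edges = e, parity_sets = gb$psets,
                 log = gb$log, ped = gb$ped),
            class = "pedigree_graph")
}

gb_from_graph <- function(pg) {
  gb <- gb_new(pg$ped)
  for (r in seq_len(nrow(pg$vertices))) {
    vv <- pg$vertices[r, ]
    key <- switch(vv$origin,
                  delivery = paste("E", gb_vkey(vv$member, vv$i, vv$j)),
                  const = paste("K", gb_vkey(vv$member, vv$i, vv$j), vv$color),
                  NULL)
    gb_add_vertex(gb, vv$member, vv$i, vv$j, vv$color, vv$origin, key = key)
    gb$forced[r] <- vv$forced
    gb$pruned[r] <- vv$pruned
  }
  # restore parity-set dedup keys
  for (ps in pg$parity_sets) {
    k <- paste(ps$kind, ps$member, paste(sort(ps$vids), collapse = ","),
               ps$offset %% 2L, sep = "|")
    assign(k, TRUE, envir = gb$pskey)
  }
  for (r in seq_len(nrow(pg$edges))) {
    ee <- pg$edges[r, ]
    gb_add_edge(gb, ee$v1, ee$v2, ee$sign, ee$trio, ee$pmember)
  }
  gb$psets <- pg$parity_sets
  gb$log <- pg$log
  gb
}

#' Build the colored signed pedigree graph
#'
#' Creates the primary site-pair vertices of every member, then inserts every
#' transmission constraint of every trio: hard relations become pinned colors
#' or parity-constraint sets, recombination costs become signed edges (one
#' per consecutive-heterozygous pair of each parent, mediated by delivery and
#' constant vertices where transmissions interact). Construction is
#' deterministic and idempotent.
#'
#' @param ped a Mendelian-consistent [pedigree()].
#' @return object of class `pedigree_graph`: `vertices`
#'   (vid/member/i/j/color/origin/forced/pruned), `edges`
#'   (eid/v1/v2/sign/trio/pmember; sign +1 = endpoints should agree, -1 =
#'   disagree; each violation is one recombination event in member `pmember`
#'   transmitting to `trio`), `parity_sets` (lists with `member`, `vids`,
#'   `offset`, `kind`; `offset` plus the number of red members must be even),
#'   `log`, and the input pedigree.
#' @export
build_pedigree_graph <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  gb <- gb_new(ped)
  gb_init_primary(gb)
  tr <- ped$trios
  for (t in seq_len(nrow(tr))) {
    gb_trio_constraints(gb, tr$father[t], tr$mother[t], tr$child[t])
  }
  gb_prune_isolated(gb)
  gb_finalize(gb)
}

#' @export
print.pedigree_graph <- function(x, ...) {
  live <- !x$vertices$pruned
  cat(sprintf(
    "<pedigree_graph> %d vertices (%d grey, %d red, %d green), %d edges (%d+/%d-), %d parity sets\n",
    sum(live), sum(live & x$vertices$color == "grey"),
    sum(live & x$vertices$color == "red"),
    sum(live & x$vertices$color == "green"),
    nrow(x$edges), sum(x$edges$sign == 1L), sum(x$edges$sign == -1L),
    length(x$parity_sets)))
  invisible(x)
}

#' Insert the signed edges contributed by one trio
#'
#' Adds every transmission constraint of the given trio to the graph (pinned
#' colors, parity sets, and cost edges). Idempotent: re-running adds nothing.
#'
#' @param pg a `pedigree_graph`.
#' @param trio_index row of `pg$ped$trios` to process.
#' @return updated `pedigree_graph`.
#' @export
add_trio_edges <- function(pg, trio_index) {
  tr <- pg$ped$trios[trio_index, ]
  gb <- gb_from_graph(pg)
  gb_trio_constraints(gb, tr$father, tr$mother, tr$child)
  gb_finalize(gb)
}

#' Prune grey vertices that carry no constraint
#'
#' A grey vertex with no incident edge and no parity-set membership is a free
#' phase variable: a recombination across its interval is undetectable. Such
#' vertices are pruned (flagged and logged); with the complete transmission
#' edge set no replacement vertex is ever required.
#'
#' @param pg a `pedigree_graph`.
#' @return updated `pedigree_graph`.
#' @export
add_additional_vertices <- function(pg) {
  gb <- gb_from_graph(pg)
  gb_prune_isolated(gb)
  gb_finalize(gb)
}

#' Apply transmission-forced colors
#'
#' Re-applies the zero-cost pinnings: a child chain vertex whose two delivery
#' values are both pinned (by a homozygous child site or a homozygous parent)
#' takes the forced color outright; conflicts are logged, not fatal. Runs to
#' fixpoint; already part of [build_pedigree_graph()].
#'
#' @param pg a `pedigree_graph`.
#' @return updated `pedigree_graph`.
#' @export
propagate_forced_colors <- function(pg) {
  gb <- gb_from_graph(pg)
  tr <- pg$ped$trios
  for (t in seq_len(nrow(tr))) {
    ds <- gb_delivery_status(gb, tr$father[t], tr$mother[t], tr$child[t])
    gc <- member_geno(pg$ped, tr$child[t])
    chets <- which(gc == 2L)
    if (length(chets) < 2L) next
    for (a in seq_len(length(chets) - 1L)) {
      x <- chets[a]; y <- chets[a + 1L]
      if (ds$type[x] == "pinned" && ds$type[y] == "pinned") {
        cvid <- gb_lookup(gb, tr$child[t], x, y)
        want <- if (ds$value[x] != ds$value[y]) "red" else "green"
        gb_pin(gb, cvid, want, "pinned deliveries")
      }
    }
  }
  gb_finalize(gb)
}

#' Parity-constraint sets of a pedigree graph
#'
#' Returns the stored sets: `chain` sets tie a supplementary vertex to the
#' primary chain spanning its interval (even red count); `link` sets tie a
#' child chain vertex to the free delivery vertices at its endpoints, with a
#' constant offset from pinned deliveries.
#'
#' @param pg a `pedigree_graph`.
#' @return list of parity sets (`member`, `vids`, `offset`, `kind`).
#' @export
build_parity_sets <- function(pg) {
  pg$parity_sets
}

#' Export a pedigree graph in DOT format
#'
#' @param pg a `pedigree_graph`.
#' @param file optional path; when `NULL` the DOT text is returned only.
#' @return character vector of DOT lines, invisibly when written to a file.
#' @export
graph_to_dot <- function(pg, file = NULL) {
  v <- pg$vertices[!pg$vertices$pruned, , drop = FALSE]
  name <- function(vid) {
    r <- match(vid, pg$vertices$vid)
    m <- pg$vertices$member[r]
    if (is.na(m)) m <- pg$vertices$origin[r]
    sprintf("\"%s_%d_%d\"", m, pg$vertices$i[r], pg$vertices$j[r])
  }
  fill <- c(grey = "lightgrey", red = "salmon", green = "palegreen")
  lines <- c("graph pedigree {",
             vapply(seq_len(nrow(v)), function(r) {
               sprintf("  %s [style=filled, fillcolor=%s];",
                       name(v$vid[r]), fill[[v$color[r]]])
             }, ""),
             vapply(seq_len(nrow(pg$edges)), function(r) {
               e <- pg$edges[r, ]
               sprintf("  %s -- %s [sign=%d, style=%s];", name(e$v1),
                       name(e$v2), e$sign,
                       if (e$sign == 1L) "solid" else "dashed")
             }, ""),
             "}")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Export a pedigree graph as a JSON-ready list / JSON text
#'
#' @param pg a `pedigree_graph`.
#' @param file optional path to write JSON to.
#' @return the list (invisibly when written).
#' @export
graph_to_json <- function(pg, file = NULL) {
  obj <- list(
    vertices = pg$vertices[!pg$vertices$pruned, , drop = FALSE],
    edges = pg$edges,
    parity_sets = pg$parity_sets,
    log = pg$log)
  if (!is.null(file)) {
    jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
    return(invisible(obj))
  }
  obj
}
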