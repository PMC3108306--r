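# Genotype coding used throughout:
#   0 = homozygous for allele 0, 1 = homozygous for allele 1, 2 = heterozygous.
# Sites are 1-based; a recombination interval (i, j) means a breakpoint strictly
# between sites i and j.

ped_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pedphase_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Construct a pedigree object
#'
#' A pedigree is an ordered collection of members, each with an identifier,
#' optional parents (either both present or both absent: only full trios are
#' modelled), a sex code, and a genotype vector over \code{\{0, 1, 2\}}.
#'
#' @param id character vector of member identifiers (unique).
#' @param father,mother character vectors of parent identifiers, `NA` (or "0")
#'   for founders. A member must have both parents or neither.
#' @param sex integer/character vector (1 = male, 2 = female, 0 = unknown);
#'   parsed and carried along but not used by the autosomal model.
#' @param geno integer matrix (members x sites) with entries in `{0,1,2}`.
#' @return An object of class `pedigree` with components `members`
#'   (data.frame id/father/mother/sex), `geno` (integer matrix, rownames are
#'   member ids) and `trios` (data.frame father/mother/child, one row per
#'   parent-offspring trio).
#' @export
pedigree <- function(id, father = NA_character_, mother = NA_character_,
                     sex = 0L, geno) {
  id <- as.character(id)
  n <- length(id)
  if (n == 0L) ped_error("ped_malformed_line", "pedigree has no members")
  if (anyDuplicated(id)) {
    ped_error("ped_malformed_line", "duplicate member id: %s",
              id[duplicated(id)][1L])
  }
  norm_parent <- function(x) {
    x <- as.character(x)
    x <- rep_len(x, n)
    x[!is.na(x) & x == "0"] <- NA_character_
    x
  }
  father <- norm_parent(father)
  mother <- norm_parent(mother)
  sex <- rep_len(as.integer(sex), n)
  if (!is.matrix(geno)) geno <- matrix(as.integer(geno), nrow = n, byrow = TRUE)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != n) {
    ped_error("ped_unequal_sites", "genotype rows (%d) != members (%d)",
              nrow(geno), n)
  }
  if (ncol(geno) < 1L) ped_error("ped_unequal_sites", "need at least one site")
  if (!all(geno %in% 0:2)) {
    ped_error("ped_missing_data", "genotype codes must be in {0,1,2}")
  }
  rownames(geno) <- id

  half <- xor(is.na(father), is.na(mother))
  if (any(half)) {
    ped_error("ped_half_trio",
              "member %s has exactly one parent; only full trios are supported",
              id[half][1L])
  }
  for (col in list(father, mother)) {
    bad <- !is.na(col) & !(col %in% id)
    if (any(bad)) {
      ped_error("ped_unknown_parent", "unknown parent id: %s", col[bad][1L])
    }
  }
  members <- data.frame(id = id, father = father, mother = mother, sex = sex,
                        stringsAsFactors = FALSE)
  has_par <- !is.na(father)
  trios <- data.frame(father = father[has_par], mother = mother[has_par],
                      child = id[has_par], stringsAsFactors = FALSE)
  ped <- structure(list(members = members, geno = geno, trios = trios),
                   class = "pedigree")
  assert_acyclic(ped)
  ped
}

assert_acyclic <- function(ped) {
  # parent relation must be acyclic even in looped (inter-marriage) pedigrees
  ids <- ped$members$id
  state <- stats::setNames(integer(length(ids)), ids)  # 0 new, 1 open, 2 done
  parents <- function(u) {
    r <- ped$members[match(u, ids), ]
    stats::na.omit(c(r$father, r$mother))
  }
  visit <- function(u) {
    if (state[[u]] == 1L) {
      ped_error("ped_unknown_parent", "parent relation has a cycle at %s", u)
    }
    if (state[[u]] == 2L) return(invisible())
    state[[u]] <<- 1L
    for (p in parents(u)) visit(p)
    state[[u]] <<- 2L
  }
  for (u in ids) visit(u)
  invisible(ped)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d members, %d sites, %d trios\n",
              nrow(x$members), ncol(x$geno), nrow(x$trios)))
  invisible(x)
}

n_sites <- function(ped) ncol(ped$geno)

member_geno <- function(ped, id) ped$geno[id, ]

#' Parse a pedigree file
#'
#' Reads whitespace-delimited pedigree files in two dialects. `linkage`:
#' `FamID IndID FatherID MotherID Sex a1 a2 a3 a4 ...` with two allele columns
#' per site, alleles coded 1/2 (1/1 -> 0, 2/2 -> 1, 1/2 or 2/1 -> 2, allele 0 =
#' missing and rejected). `compact`: `FamID IndID FatherID MotherID Sex G` with
#' one genotype string over `{0,1,2}` per member. Founder parents are coded "0".
#'
#' @param input a file path, a connection, or a character vector of lines.
#' @param dialect `"compact"` or `"linkage"`.
#' @return A [pedigree()] object; member order follows the file.
#' @export
parse_pedigree <- function(input, dialect = c("compact", "linkage")) {
  dialect <- match.arg(dialect)
  lines <- if (is.character(input) && length(input) == 1L && file.exists(input)) {
    readLines(input)
  } else if (inherits(input, "connection")) {
    readLines(input)
  } else {
    as.character(input)
  }
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (!length(lines)) ped_error("ped_malformed_line", "empty pedigree file")

  id <- father <- mother <- character(0)
  sex <- integer(0)
  geno_rows <- list()
  m <- NA_integer_

  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[ln]]), "[ \t]+")[[1L]]
    if (length(tok) < 6L) {
      ped_error("ped_malformed_line",
                "line %d: expected at least 6 fields, got %d", ln, length(tok))
    }
    id[ln] <- tok[2L]; father[ln] <- tok[3L]; mother[ln] <- tok[4L]
    sx <- suppressWarnings(as.integer(tok[5L]))
    sex[ln] <- if (is.na(sx)) 0L else sx
    if (dialect == "compact") {
      if (length(tok) != 6L) {
        ped_error("ped_malformed_line",
                  "line %d: compact dialect expects 6 fields, got %d",
                  ln, length(tok))
      }
      chars <- strsplit(tok[6L], "")[[1L]]
      bad <- which(!chars %in% c("0", "1", "2"))
      if (length(bad)) {
        cls <- if (chars[bad[1L]] %in% c("?", "9", "N", ".")) {
          "ped_missing_data"
        } else {
          "ped_malformed_line"
        }
        ped_error(cls, "line %d, genotype position %d: invalid code '%s'",
                  ln, bad[1L], chars[bad[1L]])
      }
      g <- as.integer(chars)
    } else {
      al <- tok[-(1:5)]
      if (length(al) %% 2L != 0L) {
        ped_error("ped_malformed_line",
                  "line %d: odd number of allele columns (%d)", ln, length(al))
      }
      a1 <- al[seq(1L, length(al), by = 2L)]
      a2 <- al[seq(2L, length(al), by = 2L)]
      if (any(a1 == "0" | a2 == "0")) {
        col <- 5L + 2L * which(a1 == "0" | a2 == "0")[1L] - 1L
        ped_error("ped_missing_data",
                  "line %d, column %d: missing allele (code 0)", ln, col)
      }
      ok <- a1 %in% c("1", "2") & a2 %in% c("1", "2")
      if (!all(ok)) {
        col <- 5L + 2L * which(!ok)[1L] - 1L
        ped_error("ped_malformed_line",
                  "line %d, column %d: alleles must be 1 or 2", ln, col)
      }
      g <- ifelse(a1 != a2, 2L, ifelse(a1 == "1", 0L, 1L))
    }
    if (is.na(m)) m <- length(g)
    if (length(g) != m) {
      ped_error("ped_unequal_sites",
                "line %d: %d sites, expected %d", ln, length(g), m)
    }
    geno_rows[[ln]] <- g
  }
  pedigree(id = id, father = father, mother = mother, sex = sex,
           geno = do.call(rbind, geno_rows))
}

#' Write a pedigree file
#'
#' Inverse of [parse_pedigree()]; useful for round-trips and the simulator.
#'
#' @param ped a [pedigree()].
#' @param file path or connection ("" prints to stdout).
#' @param dialect output dialect, see [parse_pedigree()].
#' @param family family identifier written in column 1.
#' @return The formatted lines, invisibly.
#' @export
write_pedigree <- function(ped, file = "", dialect = c("compact", "linkage"),
                           family = "F1") {
  dialect <- match.arg(dialect)
  mem <- ped$members
  fa <- ifelse(is.na(mem$father), "0", mem$father)
  mo <- ifelse(is.na(mem$mother), "0", mem$mother)
  lines <- vapply(seq_len(nrow(mem)), function(r) {
    g <- ped$geno[r, ]
    gtxt <- if (dialect == "compact") {
      paste(g, collapse = "")
    } else {
      paste(vapply(g, function(x) {
        switch(as.character(x), "0" = "1 1", "1" = "2 2", "2" = "1 2")
      }, ""), collapse = " ")
    }
    paste(family, mem$id[r], fa[r], mo[r], mem$sex[r], gtxt, sep = "\t")
  }, "")
  if (!identical(file, NULL)) writeLines(lines, con = file)
  invisible(lines)
}

#' Check per-site Mendelian consistency
#'
#' Recombination never alters single-site transmission, so at every site each
#' child must be able to receive one allele producible by its father and one by
#' its mother (e.g. two homozygous-0 parents cannot have a heterozygous child).
#'
#' @param ped a [pedigree()].
#' @return data.frame with one row per violation: `child`, `father`, `mother`,
#'   `site`. Zero rows means the pedigree is Mendelian-consistent.
#' @export
check_mendelian_consistency <- function(ped) {
  out <- list()
  alleles <- function(g) switch(as.character(g), "0" = 0L, "1" = 1L, "2" = 0:1)
  for (t in seq_len(nrow(ped$trios))) {
    tr <- ped$trios[t, ]
    gf <- member_geno(ped, tr$father)
    gm <- member_geno(ped, tr$mother)
    gc <- member_geno(ped, tr$child)
    for (s in seq_along(gc)) {
      ok <- FALSE
      for (af in alleles(gf[s])) for (am in alleles(gm[s])) {
        gs <- if (af == am) af else 2L
        if (gs == gc[s]) ok <- TRUE
      }
      if (!ok) {
        out[[length(out) + 1L]] <- data.frame(
          child = tr$child, father = tr$father, mother = tr$mother,
          site = s, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(child = character(0), father = character(0),
               mother = character(0), site = integer(0))
  }
}

#' Construct a haplotype pair
#'
#' @param h1,h2 binary vectors of equal length.
#' @return list with class `haplotype_pair`.
#' @export
haplotype_pair <- function(h1, h2) {
  h1 <- as.integer(h1); h2 <- as.integer(h2)
  stopifnot(length(h1) == length(h2), all(h1 %in% 0:1), all(h2 %in% 0:1))
  structure(list(h1 = h1, h2 = h2), class = "haplotype_pair")
}

#' Test consistency of a haplotype pair with a genotype
#'
#' g = 0 forces both haplotypes 0, g = 1 forces both 1, g = 2 forces them to
#' differ.
#' @param hp a [haplotype_pair()].
#' @param g genotype vector over `{0,1,2}`.
#' @return logical scalar.
#' @export
phase_consistent <- function(hp, g) {
  length(hp$h1) == length(g) &&
    all(ifelse(g == 2L, hp$h1 != hp$h2, hp$h1 == hp$h2 & hp$h1 == g))
}

# Minimum breakpoints needed for `child_h` to be a mosaic of parent's two
# haplotypes, plus the breakpoint intervals. Sites where the parent is
# homozygous leave the source unconstrained but pin the transmitted allele.
mosaic_breakpoints <- function(child_h, parent_hp) {
  m <- length(child_h)
  p1 <- parent_hp$h1; p2 <- parent_hp$h2
  # per-site possible sources: 1, 2, or both
  can1 <- p1 == child_h
  can2 <- p2 == child_h
  if (any(!can1 & !can2)) return(NULL)     # not producible at all
  constrained <- which(xor(can1, can2))    # source forced at these sites
  k <- 0L
  ivals <- list()
  if (length(constrained) >= 2L) {
    src <- ifelse(can1[constrained], 1L, 2L)
    sw <- which(src[-1L] != src[-length(src)])
    k <- length(sw)
    for (s in sw) {
      ivals[[length(ivals) + 1L]] <-
        c(constrained[s], constrained[s + 1L])
    }
  }
  list(k = k, intervals = ivals)
}

#' Count recombination events implied by a full phasing
#'
#' For each trio the two child haplotypes are assigned to the two parents (both
#' assignments are tried, the cheaper is kept) and each transmitted haplotype
#' is scored as the minimum number of source switches needed to write it as a
#' mosaic of that parent's two haplotypes. Breakpoint intervals span the two
#' nearest source-constrained sites flanking each forced switch.
#'
#' @param ped a [pedigree()].
#' @param phases named list (by member id) of [haplotype_pair()]s, each
#'   consistent with its member's genotype.
#' @return list with `k` (total events) and `events`, a data.frame
#'   `child`/`parent`/`from_site`/`to_site` sorted by child then interval.
#' @export
count_recombinations <- function(ped, phases) {
  for (u in ped$members$id) {
    if (is.null(phases[[u]])) {
      ped_error("ped_malformed_line", "no phase given for member %s", u)
    }
    if (!phase_consistent(phases[[u]], member_geno(ped, u))) {
      ped_error("ped_malformed_line",
                "phase of member %s is inconsistent with its genotype", u)
    }
  }
  total <- 0L
  events <- list()
  for (t in seq_len(nrow(ped$trios))) {
    tr <- ped$trios[t, ]
    ch <- phases[[tr$child]]
    best <- NULL
    for (assign in 1:2) {
      # assign 1: h1 from father, h2 from mother; assign 2: swapped
      hf <- if (assign == 1L) ch$h1 else ch$h2
      hm <- if (assign == 1L) ch$h2 else ch$h1
      rf <- mosaic_breakpoints(hf, phases[[tr$father]])
      rm_ <- mosaic_breakpoints(hm, phases[[tr$mother]])
      if (is.null(rf) || is.null(rm_)) next
      cand <- list(k = rf$k + rm_$k, f = rf, m = rm_)
      if (is.null(best) || cand$k < best$k) best <- cand
    }
    if (is.null(best)) {
      ped_error("ped_malformed_line",
                "child %s cannot be derived from its parents under the given phases",
                tr$child)
    }
    total <- total + best$k
    for (iv in best$f$intervals) {
      events[[length(events) + 1L]] <- data.frame(
        child = tr$child, parent = tr$father,
        from_site = iv[1L], to_site = iv[2L], stringsAsFactors = FALSE)
    }
    for (iv in best$m$intervals) {
      events[[length(events) + 1L]] <- data.frame(
        child = tr$child, parent = tr$mother,
        from_site = iv[1L], to_site = iv[2L], stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else {
    data.frame(child = character(0), parent = character(0),
               from_site = integer(0), to_site = integer(0))
  }
  ev <- ev[order(ev$child, ev$from_site, ev$to_site), , drop = FALSE]
  rownames(ev) <- NULL
  list(k = total, events = ev)
}

#' Write a haplotype configuration
#'
#' One row per member (`id TAB h1 TAB h2`), then an event block: a header line
#' `#events k=<k>` followed by one `child TAB parent TAB (i,j)` row per event,
#' sorted by child then interval.
#'
#' @param cfg a haplotype configuration as returned by [solve_rhc()] (a list
#'   with `phases`, `events`, `k`).
#' @param file path or connection ("" prints to stdout).
#' @param member_order optional character vector giving the row order.
#' @return The formatted lines, invisibly.
#' @export
write_haplotypes <- function(cfg, file = "", member_order = names(cfg$phases)) {
  rows <- vapply(member_order, function(u) {
    hp <- cfg$phases[[u]]
    paste(u, paste(hp$h1, collapse = ""), paste(hp$h2, collapse = ""),
          sep = "\t")
  }, "")
  ev <- cfg$events
  ev <- ev[order(ev$child, ev$from_site, ev$to_site), , drop = FALSE]
  evrows <- if (nrow(ev)) {
    vapply(seq_len(nrow(ev)), function(r) {
      sprintf("%s\t%s\t(%d,%d)", ev$child[r], ev$parent[r],
              ev$from_site[r], ev$to_site[r])
    }, "")
  } else {
    character(0)
  }
  lines <- unname(c(rows, sprintf("#events\tk=%d", cfg$k), evrows))
  if (!identical(file, NULL)) writeLines(lines, con = file)
  invisible(lines)
}
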