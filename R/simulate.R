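# Pedigree simulator: founder haplotypes, Mendelian transmission with planted
# recombination breakpoints, derived genotypes. Used as the test-data engine
# for every stage; same seed gives byte-identical output.

#' Simulation parameters
#'
#' @param n_founder_couples number of founder couples in generation 1.
#' @param children_per_couple children born to every couple.
#' @param generations total generations (>= 2). With `generations = 3` one
#'   child couple per founder pair reproduces: children of distinct sibships
#'   marry each other when `allow_loops` (creating multiple inheritance
#'   paths), otherwise each marries a newly created founder spouse.
#' @param m number of SNP sites.
#' @param planted_recombinations exact number of breakpoints planted, spread
#'   uniformly without replacement over (transmission, interval) slots.
#' @param allele_freq founder allele-1 frequency; 0.5 by default to maximize
#'   heterozygosity, the regime where phasing is interesting.
#' @param seed integer RNG seed; required for reproducibility.
#' @param allow_loops marry members of distinct sibships (never
#'   ancestor-descendant pairs) to create looped pedigrees.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_founder_couples = 2L, children_per_couple = 2L,
                            generations = 2L, m = 4L,
                            planted_recombinations = 1L, allele_freq = 0.5,
                            seed = 1L, allow_loops = FALSE) {
  stopifnot(n_founder_couples >= 1L, children_per_couple >= 1L,
            generations >= 2L, m >= 1L, planted_recombinations >= 0L,
            allele_freq > 0, allele_freq < 1)
  structure(list(n_founder_couples = as.integer(n_founder_couples),
                 children_per_couple = as.integer(children_per_couple),
                 generations = as.integer(generations), m = as.integer(m),
                 planted_recombinations = as.integer(planted_recombinations),
                 allele_freq = allele_freq, seed = as.integer(seed),
                 allow_loops = isTRUE(allow_loops)),
            class = "simulation_spec")
}

#' Simulate a pedigree with known haplotypes
#'
#' Founder haplotype alleles are drawn independently; every child haplotype
#' copies one parental haplotype with exactly the planted breakpoints assigned
#' to randomly chosen (transmission, interval) slots, uniformly without
#' replacement; genotypes are derived from the haplotypes.
#'
#' @param spec a [simulation_spec()].
#' @return list with `pedigree`, `phases` (the ground-truth named list of
#'   [haplotype_pair()]s), `planted` (data.frame child/parent/from_site/to_site
#'   of planted breakpoints) and `k_planted`. The planted configuration is one
#'   witness: the minimum recombination count can be lower because some planted
#'   breakpoints are undetectable.
#' @export
simulate_pedigree <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  m <- spec$m

  id <- character(0); father <- character(0); mother <- character(0)
  sex <- integer(0)
  new_member <- function(fa, mo, sx) {
    u <- sprintf("I%02d", length(id) + 1L)
    id[length(id) + 1L] <<- u
    father[length(father) + 1L] <<- fa
    mother[length(mother) + 1L] <<- mo
    sex[length(sex) + 1L] <<- sx
    u
  }
  couples <- list()
  sibship <- list()  # couple index -> children ids
  for (cpl in seq_len(spec$n_founder_couples)) {
    fa <- new_member(NA_character_, NA_character_, 1L)
    mo <- new_member(NA_character_, NA_character_, 2L)
    couples[[cpl]] <- c(fa, mo)
  }
  for (cpl in seq_along(couples)) {
    sibship[[cpl]] <- vapply(seq_len(spec$children_per_couple), function(.) {
      new_member(couples[[cpl]][1L], couples[[cpl]][2L],
                 sample(1:2, 1L))
    }, "")
  }
  if (spec$generations >= 3L) {
    gen_parents <- list()
    if (spec$allow_loops && length(sibship) >= 2L) {
      # marry the first child of sibship 1 to the first child of sibship 2
      gen_parents[[1L]] <- c(sibship[[1L]][1L], sibship[[2L]][1L])
    } else {
      for (s in seq_along(sibship)) {
        spouse <- new_member(NA_character_, NA_character_, 2L)
        gen_parents[[s]] <- c(sibship[[s]][1L], spouse)
      }
    }
    for (g in seq_len(spec$generations - 2L)) {
      next_parents <- list()
      for (cp in gen_parents) {
        kids <- vapply(seq_len(spec$children_per_couple), function(.) {
          new_member(cp[1L], cp[2L], sample(1:2, 1L))
        }, "")
        if (g < spec$generations - 2L) {
          spouse <- new_member(NA_character_, NA_character_, 1L)
          next_parents[[length(next_parents) + 1L]] <- c(kids[1L], spouse)
        }
      }
      gen_parents <- next_parents
    }
  }

  # transmissions: one per (parent, child) pair
  trans <- list()
  for (u in seq_along(id)) {
    if (!is.na(father[u])) {
      trans[[length(trans) + 1L]] <- c(father[u], id[u])
      trans[[length(trans) + 1L]] <- c(mother[u], id[u])
    }
  }
  slots <- length(trans) * (m - 1L)
  if (spec$planted_recombinations > slots) {
    ped_error("sim_infeasible",
              "cannot plant %d breakpoints in %d (transmission, interval) slots",
              spec$planted_recombinations, slots)
  }
  chosen <- if (spec$planted_recombinations > 0L) {
    sort(sample.int(slots, spec$planted_recombinations))
  } else {
    integer(0)
  }
  # slot s -> transmission ceiling(s / (m-1)), interval ((s-1) %% (m-1)) + 1
  breakpoints <- vector("list", length(trans))
  for (s in chosen) {
    tidx <- as.integer(ceiling(s / (m - 1L)))
    pos <- ((s - 1L) %% (m - 1L)) + 1L
    breakpoints[[tidx]] <- c(breakpoints[[tidx]], pos)
  }

  # build haplotypes top-down (members were created parents-first)
  phases <- list()
  trans_key <- vapply(trans, paste, "", collapse = "|")
  transmit <- function(parent_id, child_id) {
    tidx <- match(paste(parent_id, child_id, sep = "|"), trans_key)
    bps <- breakpoints[[tidx]]
    hp <- phases[[parent_id]]
    src <- sample(1:2, 1L)
    h <- integer(m)
    for (s in seq_len(m)) {
      if (s > 1L && (s - 1L) %in% bps) src <- 3L - src
      h[s] <- if (src == 1L) hp$h1[s] else hp$h2[s]
    }
    h
  }
  for (u in seq_along(id)) {
    if (is.na(father[u])) {
      phases[[id[u]]] <- haplotype_pair(
        stats::rbinom(m, 1L, spec$allele_freq),
        stats::rbinom(m, 1L, spec$allele_freq))
    } else {
      phases[[id[u]]] <- haplotype_pair(transmit(father[u], id[u]),
                                        transmit(mother[u], id[u]))
    }
  }
  geno <- vapply(id, function(u) {
    hp <- phases[[u]]
    ifelse(hp$h1 == hp$h2, hp$h1, 2L)
  }, integer(m))
  geno <- if (m == 1L) matrix(geno, ncol = 1L) else t(geno)

  planted <- if (length(chosen)) {
    do.call(rbind, lapply(chosen, function(s) {
      tidx <- as.integer(ceiling(s / (m - 1L)))
      pos <- ((s - 1L) %% (m - 1L)) + 1L
      data.frame(child = trans[[tidx]][2L], parent = trans[[tidx]][1L],
                 from_site = pos, to_site = pos + 1L, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(child = character(0), parent = character(0),
               from_site = integer(0), to_site = integer(0))
  }
  list(pedigree = pedigree(id, father, mother, sex, geno),
       phases = phases, planted = planted,
       k_planted = spec$planted_recombinations)
}

#' Random signed multigraph
#'
#' Fixture generator for line-index property tests: a uniformly random
#' simple-or-parallel signed multigraph in the same edge-list shape as a
#' pedigree graph.
#'
#' @param n_vertices,n_edges graph size; parallel edges are allowed.
#' @param p_positive probability an edge is positive.
#' @param seed RNG seed.
#' @return list of class `signed_graph` with `n_vertices` and `edges`
#'   (data.frame v1/v2/sign).
#' @export
random_signed_graph <- function(n_vertices, n_edges, p_positive = 0.5,
                                seed = 1L) {
  stopifnot(n_vertices >= 2L, n_edges >= 0L)
  set.seed(seed)
  v1 <- integer(n_edges); v2 <- integer(n_edges); sgn <- integer(n_edges)
  for (e in seq_len(n_edges)) {
    pair <- sample.int(n_vertices, 2L)
    v1[e] <- pair[1L]; v2[e] <- pair[2L]
    sgn[e] <- if (stats::runif(1) < p_positive) 1L else -1L
  }
  structure(list(n_vertices = as.integer(n_vertices),
                 edges = data.frame(v1 = v1, v2 = v2, sign = sgn)),
            class = "signed_graph")
}
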