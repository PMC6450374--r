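# Seeded simulator for F2 populations, phenotype bulks and pooled read
# counts. The generator draws from exactly the model the pooled-RF
# likelihood assumes (trinomial bulk composition, beta-binomial reads, point
# mass at the allele-count boundaries), so estimator round trips are exact
# in distribution.

#' Describe a biparental F2 cross
#'
#' @param loci Data frame with columns `name` and `rf`: ordered loci with the
#'   recombination fraction to the *previous* locus (the first value is
#'   ignored and may be `NA`). All mutant-parent alleles are in coupling.
#' @param causal Name of the locus whose mutant-parent homozygote is
#'   phenotypically recessive.
#' @return An object of class `cross_design`.
#' @examples
#' cross_design(data.frame(name = c("causal", "mk1"), rf = c(NA, 0.1)), "causal")
#' @export
cross_design <- function(loci, causal) {
  stopifnot(is.data.frame(loci), all(c("name", "rf") %in% names(loci)),
            nrow(loci) >= 1)
  rf <- loci$rf[-1L]
  if (length(rf) && (any(is.na(rf)) || any(rf < 0) || any(rf > 0.5))) {
    stop("inter-locus recombination fractions must lie in [0, 0.5]")
  }
  if (anyDuplicated(loci$name)) stop("locus names must be unique")
  if (!causal %in% loci$name) stop("'causal' must name one of the loci")
  structure(list(loci = loci, causal = causal), class = "cross_design")
}

#' Simulate an F2 population
#'
#' Each plant is the union of two independent gametes; each gamete is a
#' Markov chain along the ordered loci with per-interval switch probability
#' equal to the design's recombination fraction (two-point model, no
#' crossover interference). Phenotype is recessive iff the plant is
#' homozygous for the mutant-parent allele at the causal locus.
#'
#' @param design A [cross_design()].
#' @param n_plants Number of F2 individuals.
#' @param seed Optional integer seed.
#' @return An object of class `f2_population`: `genotypes` (plants x loci
#'   matrix of mutant-parent allele copies 0/1/2), `phenotype`
#'   (`"dominant"`/`"recessive"`), the design and the seed.
#' @export
simulate_f2_population <- function(design, n_plants, seed = NULL) {
  stopifnot(inherits(design, "cross_design"), n_plants >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(design$loci)
  gamete <- function() {
    al <- matrix(0L, n_plants, L)
    al[, 1L] <- rbinom(n_plants, 1L, 0.5)
    if (L > 1) {
      for (j in 2:L) {
        swap <- rbinom(n_plants, 1L, design$loci$rf[j]) == 1L
        al[, j] <- ifelse(swap, 1L - al[, j - 1L], al[, j - 1L])
      }
    }
    al
  }
  geno <- gamete() + gamete()
  colnames(geno) <- design$loci$name
  causal <- geno[, design$causal]
  structure(list(genotypes = geno,
                 phenotype = ifelse(causal == 2L, "recessive", "dominant"),
                 design = design, seed = seed),
            class = "f2_population")
}

#' Draw phenotype bulks from a simulated population
#'
#' Assigns plants of the matching phenotype class to pools at random and
#' without replacement (a plant belongs to at most one pool), and tallies
#' G, the number of mutant-parent alleles per locus in each pool.
#'
#' @param pop An [simulate_f2_population()] result.
#' @param pools Data frame with columns `pool`, `class`
#'   (`"recessive"`/`"dominant"`) and `n` (plants per pool).
#' @param seed Optional integer seed.
#' @return A list: `pools` (the input layout), `members` (named list of plant row
#'   indices per pool) and `G` (pools x loci matrix).
#' @export
compose_bulks <- function(pop, pools, seed = NULL) {
  stopifnot(inherits(pop, "f2_population"),
            all(c("pool", "class", "n") %in% names(pools)),
            all(pools$class %in% c("recessive", "dominant")), all(pools$n >= 1))
  if (!is.null(seed)) set.seed(seed)
  members <- vector("list", nrow(pools))
  names(members) <- pools$pool
  for (cl in unique(pools$class)) {
    rows <- which(pools$class == cl)
    avail <- which(pop$phenotype == cl)
    need <- sum(pools$n[rows])
    if (length(avail) < need) {
      stop(sprintf("need %d plants of class '%s' but only %d available",
                   need, cl, length(avail)))
    }
    picked <- sample(avail, need)
    off <- 0L
    for (r in rows) {
      members[[r]] <- picked[(off + 1L):(off + pools$n[r])]
      off <- off + pools$n[r]
    }
  }
  G <- t(vapply(members, function(ix) {
    colSums(pop$genotypes[ix, , drop = FALSE])
  }, numeric(ncol(pop$genotypes))))
  rownames(G) <- pools$pool
  list(pools = pools, members = members, G = G)
}

#' Simulate pooled read counts at one SNV for one bulk
#'
#' The library allele concentration is drawn from
#' `Beta(G * xi, (2n - G) * xi)` for `0 < G < 2n` and is the exact value
#' `G / (2n)` at the boundaries (the degenerate Beta limit); the
#' mutant-parent read count is then binomial in the coverage.
#'
#' @param G Mutant-parent allele count(s), `0..2n` (vectorised).
#' @param n Bulk size.
#' @param xi Mixing accuracy coefficient (> 0).
#' @param coverage Read depth(s), recycled against `G`.
#' @param seed Optional integer seed.
#' @return Integer matrix with columns `m` and `c`.
#' @export
simulate_pool_reads <- function(G, n, xi, coverage, seed = NULL) {
  stopifnot(all(G >= 0), all(G <= 2 * n), xi > 0, all(coverage >= 0))
  if (!is.null(seed)) set.seed(seed)
  k <- length(G)
  cc <- rep_len(as.integer(coverage), k)
  gamma <- G / (2 * n)
  mid <- G > 0 & G < 2 * n
  if (any(mid)) {
    gamma[mid] <- rbeta(sum(mid), G[mid] * xi, (2 * n - G[mid]) * xi)
  }
  cbind(m = rbinom(k, cc, gamma), c = cc)
}

# Cross-library contamination: each read of library j is independently
# replaced, with probability hop_rate, by a read drawn from the pooled
# allele mix of all other libraries (their pre-hop composition).
.apply_index_hopping <- function(m, c, hop_rate) {
  if (hop_rate == 0) return(m)
  out <- integer(length(m))
  for (j in seq_along(m)) {
    oc <- sum(c[-j])
    p_other <- if (oc > 0) sum(m[-j]) / oc else 0.5
    nh <- rbinom(1L, c[j], hop_rate)
    kept <- rhyper(1L, m[j], c[j] - m[j], c[j] - nh)
    out[j] <- kept + rbinom(1L, nh, p_other)
  }
  out
}

#' Simulate a full bulked-segregant sequencing experiment
#'
#' Chains [simulate_f2_population()], [compose_bulks()] and
#' [simulate_pool_reads()]; each non-causal locus carries `snvs_per_locus`
#' SNVs read independently. Optional index hopping replaces reads with reads
#' drawn from the allele mix of the other libraries.
#'
#' @param design A [cross_design()].
#' @param n_plants F2 population size.
#' @param pools Pool specification as in [compose_bulks()].
#' @param xi Mixing accuracy coefficient.
#' @param coverage Per-SNV, per-pool read depth (scalar, or a function of no
#'   arguments returning one draw).
#' @param hop_rate Per-read probability of cross-library replacement,
#'   in \[0, 1).
#' @param snvs_per_locus SNVs simulated per marker locus.
#' @param seed Optional integer seed governing the whole experiment.
#' @return An object of class `bsa_experiment`: the `population`, the
#'   `bulks`, a long `counts` data frame (`snv`, `locus`, `pool`, `class`,
#'   `n`, `m`, `c`) ready for [estimate_rf_all()], and the parameters.
#' @export
simulate_bsa_experiment <- function(design, n_plants, pools, xi = 10,
                                    coverage = 100, hop_rate = 0,
                                    snvs_per_locus = 1, seed = NULL) {
  stopifnot(hop_rate >= 0, hop_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  pop <- simulate_f2_population(design, n_plants)
  bulks <- compose_bulks(pop, pools)
  loci <- setdiff(design$loci$name, design$causal)
  draw_cov <- if (is.function(coverage)) coverage else function() coverage
  rows <- list()
  for (loc in loci) {
    for (s in seq_len(snvs_per_locus)) {
      snv <- if (snvs_per_locus > 1) sprintf("%s_snv%d", loc, s) else loc
      m <- integer(nrow(pools))
      cc <- integer(nrow(pools))
      for (j in seq_len(nrow(pools))) {
        r <- simulate_pool_reads(bulks$G[j, loc], pools$n[j], xi, draw_cov())
        m[j] <- r[, "m"]
        cc[j] <- r[, "c"]
      }
      m <- .apply_index_hopping(m, cc, hop_rate)
      rows[[length(rows) + 1L]] <- data.frame(
        snv = snv, locus = loc, pool = pools$pool, class = pools$class,
        n = pools$n, m = m, c = cc)
    }
  }
  structure(list(population = pop, bulks = bulks,
                 counts = do.call(rbind, rows),
                 params = list(xi = xi, hop_rate = hop_rate, seed = seed)),
            class = "bsa_experiment")
}

#' Convert a simulated experiment to variant records
#'
#' Builds the variant-record table the filtering stage consumes: one
#' biallelic SNV per simulated marker with clean homozygous parent
#' libraries (mutant parent carries the alternate allele) and per-pool
#' allele depths taken from the simulated counts.
#'
#' @param exp A [simulate_bsa_experiment()] result.
#' @param parent_depth Read depth given to each parent library.
#' @param qual QUAL score given to every record.
#' @return A list with `records` (data frame) and `roles` (library role
#'   mapping), as expected by [filter_snvs()].
#' @export
experiment_to_records <- function(exp, parent_depth = 60, qual = 60) {
  stopifnot(inherits(exp, "bsa_experiment"))
  counts <- exp$counts
  ids <- unique(counts$snv)
  pools <- unique(counts[, c("pool", "class", "n")])
  rec <- data.frame(snv = ids, contig = ids, pos = seq_along(ids),
                    ref = "A", alt = "G", qual = qual)
  rec[["parentM.ref"]] <- 0L
  rec[["parentM.alt"]] <- parent_depth
  rec[["parentW.ref"]] <- parent_depth
  rec[["parentW.alt"]] <- 0L
  for (p in pools$pool) {
    sub <- counts[counts$pool == p, ]
    sub <- sub[match(ids, sub$snv), ]
    rec[[paste0(p, ".ref")]] <- sub$c - sub$m
    rec[[paste0(p, ".alt")]] <- sub$m
  }
  list(records = rec,
       roles = list(parent_mut = "parentM", parent_wt = "parentW",
                    pools = pools))
}

#' Write the simulator's tab-separated output tables
#'
#' Writes `plants.tsv` (plant id, one genotype column per locus coded 0/1/2
#' mutant-parent allele copies, `phenotype`), `pools.tsv` (`pool`, `class`,
#' `n`, comma-separated `members`) and `counts.tsv` (`snv`, `pool`, `class`,
#' `n`, `m`, `c`).
#'
#' @param exp A [simulate_bsa_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(exp, dir) {
  stopifnot(inherits(exp, "bsa_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plants <- data.frame(plant = seq_len(nrow(exp$population$genotypes)),
                       exp$population$genotypes,
                       phenotype = exp$population$phenotype,
                       check.names = FALSE)
  pooltab <- exp$bulks$pools
  pooltab$members <- vapply(exp$bulks$members, paste, "", collapse = ",")
  paths <- file.path(dir, c("plants.tsv", "pools.tsv", "counts.tsv"))
  write.table(plants, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pooltab, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(exp$counts[, c("snv", "pool", "class", "n", "m", "c")],
              paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Run a simulated experiment from a YAML configuration
#'
#' The configuration carries the keys `loci` (list of `name`/`rf` pairs),
#' `causal`, `n_plants`, `pools` (list of `pool`/`class`/`n`), `xi`,
#' `coverage`, `hop_rate` and `seed`.
#'
#' @param path Path to the YAML file.
#' @return A [simulate_bsa_experiment()] result.
#' @export
simulate_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  loci <- do.call(rbind, lapply(cfg$loci, function(l) {
    data.frame(name = l$name, rf = if (is.null(l$rf)) NA_real_ else l$rf)
  }))
  pools <- do.call(rbind, lapply(cfg$pools, function(p) {
    data.frame(pool = p$pool, class = p$class, n = p$n)
  }))
  simulate_bsa_experiment(cross_design(loci, cfg$causal), cfg$n_plants, pools,
                          xi = cfg$xi %||% 10,
                          coverage = cfg$coverage %||% 100,
                          hop_rate = cfg$hop_rate %||% 0,
                          seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
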