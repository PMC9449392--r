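#' Simulation configuration
#'
#' Parameters of the forward-in-time Wright-Fisher simulation of two
#' diverged parental populations and an admixed hybrid, mirroring a
#' composite breed formed by crossing two source breeds and then breeding
#' the cross closed. Rates are per bp per generation; population sizes are
#' diploid. The defaults are desk-scale: a small population with an
#' inflated mutation rate gives a realistic number of segregating sites on
#' a 2-Mb contig in seconds.
#'
#' @param N Diploid population size of every population (default 100).
#' @param L Contig length in bp (default 2e6).
#' @param mu Per-bp per-generation mutation rate (default 1e-7; scaled up
#'   so that `4*N*mu` matches a realistic per-site diversity).
#' @param rho Per-bp per-generation recombination rate (default 5e-8).
#'   Like `mu` it is scaled up from the mammalian ~1e-8 to compensate for
#'   the scaled-down population size; the `rho/mu` ratio of 0.5 keeps
#'   haplotype blocks and sweep footprints on the scale of the 100-kb
#'   analysis windows.
#' @param split_gens Generations each parental population drifts after the
#'   split (default 600, i.e. 3 x 2N: deeply diverged parental breeds, the
#'   situation a hybrid-breed scan assumes).
#' @param admix_prop Probability a hybrid founder haplotype is drawn from
#'   parent A (default 0.5).
#' @param admix_gens Generations of closed breeding of the hybrid after
#'   founding (default 20, the scaled age of a recently formed composite
#'   breed).
#' @param burnin_gens Burn-in generations of the ancestral population,
#'   starting from a monomorphic state (default `4 * N`).
#' @param sweep Optional [sweep_spec()]; `NULL` for neutral simulation.
#' @param seed Integer random seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(N = 100, L = 2e6, mu = 1e-7, rho = 5e-8,
                       split_gens = 600, admix_prop = 0.5, admix_gens = 20,
                       burnin_gens = 4 * N, sweep = NULL, seed = 1) {
  stopifnot(N >= 2, L > 0, mu >= 0, rho >= 0, split_gens >= 0,
            admix_prop >= 0, admix_prop <= 1, admix_gens >= 0,
            burnin_gens >= 0)
  if (!is.null(sweep)) {
    stopifnot(inherits(sweep, "sweep_spec"))
    if (sweep$position < 0 || sweep$position >= L) {
      stop("sweep position must lie in [0, L)", call. = FALSE)
    }
  }
  structure(list(N = as.integer(N), L = as.integer(L), mu = mu, rho = rho,
                 split_gens = as.integer(split_gens),
                 admix_prop = admix_prop,
                 admix_gens = as.integer(admix_gens),
                 burnin_gens = as.integer(burnin_gens),
                 sweep = sweep, seed = as.integer(seed)),
            class = "sim_config")
}

#' Hard-sweep specification
#'
#' @param population Which population carries the sweep: `"HYB"`, `"P1"`
#'   or `"P2"`.
#' @param position Position of the beneficial allele in bp (0-based).
#' @param s Selection coefficient of the homozygote (fitnesses 1, 1+h*s,
#'   1+s).
#' @param h Dominance coefficient (default 0.5, additive).
#' @param target_freq The sweep phase is run until the beneficial allele
#'   exceeds this frequency (default 0.95, a near-complete sweep);
#'   trajectories that lose the allele are restarted so sweep datasets
#'   always contain a sweep.
#' @param init_copies Number of carrier haplotypes at the start of the
#'   sweep phase. The variant is modelled as standing variation of single
#'   ancestral origin: every carrier shares the origin haplotype over an
#'   exponentially distributed tract around the site (mean
#'   `1/(rho * origin_age)` per side, the expected unrecombined segment
#'   for a variant `origin_age` generations old) and keeps its own
#'   background elsewhere. The default `NULL` uses 20% of the haplotype
#'   pool; `1` is the classic sweep from a brand-new mutation (much slower
#'   at small population sizes, hence a weaker footprint).
#' @param origin_age Age of the standing variant in generations (default
#'   150, roughly the expected age of a neutral variant at 20% frequency
#'   when 2N = 200): sets the mean shared-tract length
#'   `1/(rho * origin_age)` per side around the selected site among the
#'   founding carriers.
#' @param max_gens Upper bound on sweep-phase generations (default 2000).
#' @param max_restarts Upper bound on restarts after allele loss.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(population = "HYB", position, s = 0.1, h = 0.5,
                       target_freq = 0.95, init_copies = NULL,
                       origin_age = 150, max_gens = 2000,
                       max_restarts = 500) {
  stopifnot(population %in% c("HYB", "P1", "P2"), s >= 0, h >= 0,
            target_freq > 0, target_freq <= 1,
            is.null(init_copies) || init_copies >= 1, origin_age >= 0)
  structure(list(population = population, position = as.integer(position),
                 s = s, h = h, target_freq = target_freq,
                 init_copies = if (is.null(init_copies)) NULL
                 else as.integer(init_copies),
                 origin_age = origin_age,
                 max_gens = as.integer(max_gens),
                 max_restarts = as.integer(max_restarts)),
            class = "sweep_spec")
}

#' One Wright-Fisher generation
#'
#' Builds `nrow(haps)` offspring haplotypes: each samples a diploid parent
#' (uniformly, or proportionally to fitness `1, 1+h*s, 1+s` by genotype at
#' the sweep site), recombines the parent's two haplotypes with a
#' `Poisson(rho * L)` number of crossovers at uniform positions, and adds
#' `Poisson(mu * L)` new mutations at uniform positions not already
#' segregating (infinite-sites with collision re-draw).
#'
#' @param haps Integer 0/1 matrix, haplotypes in rows (an even number),
#'   sites in columns.
#' @param positions Integer site positions (bp, sorted) matching columns.
#' @param L Contig length in bp.
#' @param mu,rho Mutation and recombination rates per bp per generation.
#' @param sweep_col Optional column index of the site under selection.
#' @param s,h Selection and dominance coefficients (used with
#'   `sweep_col`).
#' @param forbidden Optional extra positions new mutations must avoid
#'   (sites segregating in other populations sharing the coordinate
#'   system).
#' @return List with the offspring `haps`, `positions`, and `new_pos`
#'   (positions of mutations added this generation).
#' @export
wf_generation <- function(haps, positions, L, mu, rho, sweep_col = NULL,
                          s = 0, h = 0.5, forbidden = NULL) {
  n_h <- nrow(haps)
  if (n_h %% 2L != 0L) stop("haplotype count must be even", call. = FALSE)
  n_ind <- n_h %/% 2L
  s_cols <- ncol(haps)
  if (!is.null(sweep_col) && s > 0) {
    dos <- haps[seq(1L, n_h, 2L), sweep_col] +
      haps[seq(2L, n_h, 2L), sweep_col]
    w <- 1 + c(0, h * s, s)[dos + 1L]
  } else {
    w <- rep(1, n_ind)
  }
  par_ind <- sample.int(n_ind, n_h, replace = TRUE, prob = w)
  start_h <- sample.int(2L, n_h, replace = TRUE)
  n_x <- stats::rpois(n_h, rho * L)
  new_haps <- matrix(0L, n_h, s_cols)
  plain <- n_x == 0L
  if (any(plain)) {
    new_haps[plain, ] <- haps[2L * par_ind[plain] - 2L + start_h[plain], ,
                              drop = FALSE]
  }
  for (i in which(!plain)) {
    br <- sort(stats::runif(n_x[i], 0, L))
    seg <- findInterval(positions, br)
    from2 <- (seg + start_h[i]) %% 2L == 0L
    row <- haps[2L * par_ind[i] - 2L + start_h[i], ]
    other <- haps[2L * par_ind[i] - 1L + (start_h[i] %% 2L), ]
    row[from2 != (start_h[i] == 2L)] <-
      other[from2 != (start_h[i] == 2L)]
    new_haps[i, ] <- row
  }
  n_mut <- stats::rpois(1L, n_h * mu * L)
  new_pos <- integer(0)
  if (n_mut > 0L) {
    taken <- c(positions, forbidden)
    cand <- integer(0)
    while (length(cand) < n_mut) {
      draw <- sample.int(L, n_mut - length(cand))
      draw <- setdiff(draw, c(taken, cand))
      cand <- c(cand, draw)
    }
    new_pos <- cand
    carriers <- sample.int(n_h, n_mut, replace = TRUE)
    mut_block <- matrix(0L, n_h, n_mut)
    mut_block[cbind(carriers, seq_len(n_mut))] <- 1L
    new_haps <- cbind(new_haps, mut_block)
    positions <- c(positions, new_pos)
    ord <- order(positions)
    positions <- positions[ord]
    new_haps <- new_haps[, ord, drop = FALSE]
  }
  list(haps = new_haps, positions = positions, new_pos = new_pos)
}

# crossover mask helper note: start_h is the haplotype the offspring reads
# at the left contig end; from2 marks segments read from the other one.

#' Simulate an ancestral haplotype pool
#'
#' Runs `n_burnin_gens` neutral Wright-Fisher generations from a
#' monomorphic start, pruning fixed and lost sites, and returns the final
#' pool of `2 * N` haplotypes over the segregating sites.
#'
#' @param config A [sim_config()].
#' @param n_burnin_gens Number of burn-in generations (default
#'   `config$burnin_gens`).
#' @return List with `haps` (2N x S matrix) and `positions` (sorted bp).
#' @export
simulate_ancestral <- function(config, n_burnin_gens = config$burnin_gens) {
  pop <- list(haps = matrix(0L, 2L * config$N, 0L), positions = integer(0))
  for (g in seq_len(n_burnin_gens)) {
    step <- wf_generation(pop$haps, pop$positions, config$L, config$mu,
                          config$rho)
    keep <- seg_sites(step$haps)
    pop <- list(haps = step$haps[, keep, drop = FALSE],
                positions = step$positions[keep])
  }
  if (ncol(pop$haps) == 0L) {
    stop("no segregating sites after burn-in; increase mu * L or ",
         "burnin_gens", call. = FALSE)
  }
  pop
}

seg_sites <- function(haps) {
  cs <- colSums(haps)
  which(cs > 0L & cs < nrow(haps))
}

#' Found an admixed population and let it drift
#'
#' Each founder haplotype is drawn (with replacement) from parent A's pool
#' with probability `admix_prop`, otherwise from parent B's, then the
#' hybrid mates internally for `admix_gens` Wright-Fisher generations.
#' Parents must share a coordinate system (site columns).
#'
#' @param pop_a,pop_b Parent populations: lists with `haps` and
#'   `positions` over identical positions.
#' @param admix_prop Probability of drawing from parent A.
#' @param admix_gens Generations of internal mating after founding.
#' @param config A [sim_config()] providing `N`, `L`, `mu`, `rho`.
#' @return The hybrid population (list with `haps`, `positions`); sites may
#'   extend beyond the parents' when new mutations arise (absent columns
#'   in the parents are implicit zeros for downstream merging).
#' @export
admix <- function(pop_a, pop_b, admix_prop, admix_gens, config) {
  if (!length(pop_a$positions) || !nrow(pop_a$haps) || !nrow(pop_b$haps)) {
    stop("empty parent population", call. = FALSE)
  }
  if (!identical(pop_a$positions, pop_b$positions)) {
    stop("parents must share a coordinate system", call. = FALSE)
  }
  n_h <- 2L * config$N
  from_a <- stats::runif(n_h) < admix_prop
  rows <- ifelse(from_a,
                 sample.int(nrow(pop_a$haps), n_h, replace = TRUE),
                 sample.int(nrow(pop_b$haps), n_h, replace = TRUE))
  haps <- matrix(0L, n_h, length(pop_a$positions))
  haps[from_a, ] <- pop_a$haps[rows[from_a], , drop = FALSE]
  haps[!from_a, ] <- pop_b$haps[rows[!from_a], , drop = FALSE]
  pop <- list(haps = haps, positions = pop_a$positions)
  for (g in seq_len(admix_gens)) {
    step <- wf_generation(pop$haps, pop$positions, config$L, config$mu,
                          config$rho,
                          forbidden = pop_a$positions)
    keep <- colSums(step$haps) > 0L
    pop <- list(haps = step$haps[, keep, drop = FALSE],
                positions = step$positions[keep])
  }
  pop
}

#' Run the full three-population simulation
#'
#' Burn-in of an ancestral population, split into two parents (P1, P2)
#' drifting `split_gens` generations, then founding of an admixed hybrid
#' (HYB) drifting `admix_gens` generations, with an optional hard sweep.
#' When a sweep is requested the carrier population's phase is rerun until
#' the beneficial allele exceeds `target_freq` (trajectories losing the
#' allele restart; the restart count is recorded in the truth). All three
#' populations share one sorted site coordinate system; sites monomorphic
#' across the whole dataset are pruned.
#'
#' @param config A [sim_config()].
#' @return An object of class `wf_sim`: list with `positions` (sorted bp,
#'   1-based in VCF output), `pops` (named list of 2N x S haplotype
#'   matrices for P1, P2, HYB), `truth` (sweep truth or `NULL`) and
#'   `config`.
#' @export
wf_simulate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  anc <- simulate_ancestral(config)
  sw <- config$sweep

  evolve <- function(pop, gens, forbidden, sweep_here) {
    restarts <- 0L
    repeat {
      cur <- pop
      if (!is.null(sweep_here)) {
        cur <- insert_sweep_allele(cur, sweep_here, rho = config$rho,
                                   age = sweep_here$origin_age)
      }
      ok <- TRUE
      g <- 0L
      repeat {
        g <- g + 1L
        done_gens <- g > gens
        freq <- NA_real_
        if (!is.null(sweep_here)) {
          col <- match(sweep_here$position + 1L, cur$positions)
          if (is.na(col)) { ok <- FALSE; break }
          freq <- mean(cur$haps[, col])
          if (freq == 0) { ok <- FALSE; break }
          if (done_gens && freq > sweep_here$target_freq) break
          if (g > sweep_here$max_gens) { ok <- FALSE; break }
        } else if (done_gens) break
        col <- if (is.null(sweep_here)) NULL
        else match(sweep_here$position + 1L, cur$positions)
        step <- wf_generation(cur$haps, cur$positions, config$L,
                              config$mu, config$rho, sweep_col = col,
                              s = if (is.null(sweep_here)) 0
                              else sweep_here$s,
                              h = if (is.null(sweep_here)) 0.5
                              else sweep_here$h,
                              forbidden = forbidden)
        # drop sites lost in this population; other populations keep
        # their own copies and alignment re-merges by position
        keep <- colSums(step$haps) > 0L
        cur <- list(haps = step$haps[, keep, drop = FALSE],
                    positions = step$positions[keep])
      }
      if (ok) return(list(pop = cur, restarts = restarts))
      restarts <- restarts + 1L
      if (restarts > sweep_here$max_restarts) {
        stop("sweep allele lost in every attempt; increase s or ",
             "init_copies", call. = FALSE)
      }
    }
  }

  sweep_for <- function(popname) {
    if (!is.null(sw) && sw$population == popname) sw else NULL
  }

  p1 <- evolve(anc, config$split_gens, forbidden = integer(0),
               sweep_for("P1"))
  p2 <- evolve(anc, config$split_gens,
               forbidden = p1$pop$positions, sweep_for("P2"))

  aligned <- align_pops(list(P1 = p1$pop, P2 = p2$pop))
  hyb_founder_a <- list(haps = aligned$pops$P1,
                        positions = aligned$positions)
  hyb_founder_b <- list(haps = aligned$pops$P2,
                        positions = aligned$positions)

  hyb_spec <- sweep_for("HYB")
  founders <- admix(hyb_founder_a, hyb_founder_b, config$admix_prop,
                    admix_gens = 0L, config = config)
  res <- evolve(founders, config$admix_gens,
                forbidden = aligned$positions, hyb_spec)
  restarts <- p1$restarts + p2$restarts + res$restarts

  final <- align_pops(list(P1 = hyb_founder_a, P2 = hyb_founder_b,
                           HYB = res$pop))
  keep <- overall_segregating(final$pops)
  positions <- final$positions[keep]
  pops <- lapply(final$pops, function(h) h[, keep, drop = FALSE])

  truth <- NULL
  if (!is.null(sw)) {
    col <- match(sw$position + 1L, positions)
    freq <- if (is.na(col)) 1 else mean(pops[[sw$population]][, col])
    # the swept tract: carriers share the origin haplotype over segments
    # of mean 1/(rho * origin_age) per side around the selected site
    k_init <- if (is.null(sw$init_copies)) 2L else sw$init_copies
    seg <- if (k_init > 1L && config$rho * sw$origin_age > 0)
      1 / (config$rho * sw$origin_age) else 0
    truth <- list(population = sw$population, position = sw$position,
                  interval = c(max(0, sw$position - seg),
                               min(config$L, sw$position + 1 + seg)),
                  final_freq = freq, restarts = restarts,
                  s = sw$s, h = sw$h)
  }
  structure(list(positions = positions, pops = pops, truth = truth,
                 config = config, restarts = restarts),
            class = "wf_sim")
}

# give each population zero columns for sites present only in the others
align_pops <- function(pops) {
  all_pos <- sort(unique(unlist(lapply(pops, `[[`, "positions"))))
  out <- lapply(pops, function(p) {
    m <- matrix(0L, nrow(p$haps), length(all_pos))
    m[, match(p$positions, all_pos)] <- p$haps
    m
  })
  list(positions = all_pos, pops = out)
}

overall_segregating <- function(hap_list) {
  tot <- Reduce(`+`, lapply(hap_list, colSums))
  n <- sum(vapply(hap_list, nrow, integer(1)))
  tot > 0L & tot < n
}

# Seed the beneficial allele as a standing variant of single ancestral
# origin: every carrier haplotype shares the origin haplotype over an
# exponentially distributed segment around the site (mean 1/(rho * age)
# per side, the expected unrecombined tract after `age` generations),
# keeping its own background outside the tract. With init_copies = 1 this
# reduces to a brand-new mutation on one haplotype.
insert_sweep_allele <- function(pop, sw, rho = 0, age = 0) {
  pos1 <- sw$position + 1L
  n_h <- nrow(pop$haps)
  k <- if (is.null(sw$init_copies)) max(1L, round(0.2 * n_h))
  else min(sw$init_copies, n_h)
  carriers <- sample.int(n_h, k)
  if (k > 1L) {
    origin <- pop$haps[carriers[1L], ]
    rate <- rho * age
    for (i in carriers[-1L]) {
      if (rate > 0) {
        lo <- pos1 - stats::rexp(1L, rate)
        hi <- pos1 + stats::rexp(1L, rate)
      } else {
        lo <- -Inf; hi <- Inf
      }
      span <- pop$positions >= lo & pop$positions <= hi
      pop$haps[i, span] <- origin[span]
    }
  }
  col <- match(pos1, pop$positions)
  if (is.na(col)) {
    newcol <- matrix(0L, n_h, 1L)
    newcol[carriers, 1L] <- 1L
    positions <- c(pop$positions, pos1)
    haps <- cbind(pop$haps, newcol)
    ord <- order(positions)
    pop <- list(haps = haps[, ord, drop = FALSE],
                positions = positions[ord])
  } else {
    pop$haps[, col] <- 0L
    pop$haps[carriers, col] <- 1L
  }
  pop
}

#' @export
print.wf_sim <- function(x, ...) {
  cat(sprintf("wf_sim: %d populations x %d haplotypes, %d segregating sites on %g bp\n",
              length(x$pops), nrow(x$pops[[1]]), length(x$positions),
              as.numeric(x$config$L)))
  if (!is.null(x$truth)) {
    cat(sprintf("  sweep in %s at bp %d (s=%.3g), final freq %.3f, %d restart(s)\n",
                x$truth$population, x$truth$position, x$truth$s,
                x$truth$final_freq, x$truth$restarts))
  }
  invisible(x)
}

#' Convert a simulation to a phased variant matrix and population map
#'
#' @param sim A `wf_sim` object.
#' @param contig Contig name for the output (default `"sim1"`).
#' @return List with `vm` (a phased [variant_matrix()]) and `popmap`
#'   (a [population_map()]).
#' @export
as_variant_matrix <- function(sim, contig = "sim1") {
  pops <- sim$pops
  n_per <- vapply(pops, function(h) nrow(h) %/% 2L, integer(1))
  ids <- unlist(lapply(names(pops), function(p)
    paste0(p, "_", seq_len(n_per[[p]]))))
  haps <- t(do.call(rbind, pops))   # variants x total haplotypes
  h1 <- haps[, seq(1L, ncol(haps), 2L), drop = FALSE]
  h2 <- haps[, seq(2L, ncol(haps), 2L), drop = FALSE]
  geno <- h1 + h2
  vm <- variant_matrix(contig, sim$positions, geno, ids,
                       haplotypes = haps,
                       quality = rep(60, length(sim$positions)))
  pm <- population_map(stats::setNames(rep(names(pops), n_per), ids))
  list(vm = vm, popmap = pm)
}

#' Write the simulated dataset as pipeline input files
#'
#' Writes a phased VCF, a two-column population map, an FAI-style contig
#' length file and a JSON truth record into `dir`.
#'
#' @param sim A `wf_sim` object.
#' @param dir Output directory (created if needed).
#' @param contig Contig name (default `"sim1"`).
#' @return Named character vector of the file paths written.
#' @export
generate_dataset <- function(sim, dir, contig = "sim1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conv <- as_variant_matrix(sim, contig = contig)
  paths <- c(vcf = file.path(dir, "dataset.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             fai = file.path(dir, "contigs.fai"),
             truth = file.path(dir, "truth.json"))
  write_vcf(conv$vm, paths["vcf"], contig_length = sim$config$L)
  utils::write.table(
    data.frame(sample = names(conv$popmap),
               population = unclass(conv$popmap)),
    paths["popmap"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  writeLines(paste(contig, sim$config$L, sep = "\t"), paths["fai"])
  truth <- if (is.null(sim$truth)) list(sweep = FALSE)
  else c(list(sweep = TRUE), sim$truth)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             paths["truth"])
  paths
}
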