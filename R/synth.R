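#' Configuration for the synthetic-data generator
#'
#' One seeded configuration drives every generator; each generator draws
#' from its own substream (derived from `seed` and the generator name), so
#' adding a generator never perturbs the others. The defaults are the
#' study conditions the pipeline is validated under: a 4-timepoint
#' (0/6/12/18 h) x 3-replicate diurnal design, ~200-residue crTPs with 10%
#' per-position substitution noise, 50 planted crTPs plus 20 filter-decoys
#' in a 500-protein proteome, 200 gene trees (40% HGT, 20% EGT, 10%
#' filter-fodder), and a genome whose viral blocks are covered at depth
#' 0.03 versus 0.7 for non-viral blocks.
#'
#' @param seed Root RNG seed (R's Mersenne-Twister; all substream seeds
#'   stay below 2^31).
#' @param n_species,n_families,gain_loss_rates Species-tree / gene-family
#'   simulation: `gain_loss_rates` is `c(gain, loss)`; origination is
#'   uniform over branches (the single-gain Dollo constraint), the gain
#'   element is a reserved weight, and `loss` is the per-branch loss
#'   probability.
#' @param n_proteins,crtp_length,n_planted_crtp,n_decoy_crtp,n_seed_crtps,crtp_noise,max_protein_length
#'   Proteome simulation parameters.
#' @param n_genes_expr,frac_rhythmic,amplitude_over_sigma,noise_cv,timepoints_h,n_replicates
#'   Time-course simulation parameters; `amplitude_over_sigma` is the
#'   planted relative amplitude divided by the noise coefficient of
#'   variation.
#' @param n_gene_trees,frac_hgt,frac_egt,frac_fodder Gene-tree simulation
#'   mix (the remainder is negative trees).
#' @param genome_len,frac_viral,read_len,read_depth_viral,read_depth_nonviral
#'   Region/read simulation parameters (depths are expected fold
#'   coverages).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_species = 8, n_families = 300,
                         gain_loss_rates = c(1, 0.1),
                         n_proteins = 500, crtp_length = 200,
                         n_planted_crtp = 50, n_decoy_crtp = 20,
                         n_seed_crtps = 5, crtp_noise = 0.1,
                         max_protein_length = 1000,
                         n_genes_expr = 1200, frac_rhythmic = 1 / 6,
                         amplitude_over_sigma = 3, noise_cv = 0.2,
                         timepoints_h = c(0, 6, 12, 18), n_replicates = 3,
                         n_gene_trees = 200, frac_hgt = 0.4,
                         frac_egt = 0.2, frac_fodder = 0.1,
                         genome_len = 200000, frac_viral = 0.3,
                         read_len = 100, read_depth_viral = 0.03,
                         read_depth_nonviral = 0.7) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 3, cfg$n_families >= 1,
            cfg$gain_loss_rates[2] >= 0, cfg$gain_loss_rates[2] <= 1,
            cfg$frac_rhythmic >= 0, cfg$frac_rhythmic <= 1,
            cfg$amplitude_over_sigma >= 0,
            cfg$n_planted_crtp + cfg$n_decoy_crtp <= cfg$n_proteins,
            cfg$frac_hgt + cfg$frac_egt + cfg$frac_fodder <= 1,
            cfg$frac_viral > 0, cfg$frac_viral < 1)
  if (cfg$read_len > cfg$genome_len)
    stop("read_len exceeds genome_len")
  if (cfg$crtp_length + 250 + 50 > cfg$max_protein_length)
    stop("crtp_length + minimum mature length + maximum prefix exceeds ",
         "max_protein_length")
  structure(cfg, class = "synth_config")
}

random_aa <- function(n, background = AA_BACKGROUND) {
  paste(sample(AA_ALPHABET[1:20], n, replace = TRUE,
               prob = background[AA_ALPHABET[1:20]]), collapse = "")
}

mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- sample(AA_ALPHABET[1:20], sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

#' Simulate a rooted species tree
#'
#' @param config A [synth_config()].
#' @return Rooted `phylo` with tips `sp1..spN`.
#' @export
simulate_species_tree <- function(config) {
  with_seed(derive_seed(config$seed, "species_tree"), {
    tree <- ape::rtree(config$n_species,
                       tip.label = paste0("sp", seq_len(config$n_species)))
    tree
  })
}

#' Simulate gene-family evolution under single-gain/multiple-loss dynamics
#'
#' Each family originates once on a uniformly chosen branch (equivalently,
#' at the node the branch leads into; the root is included so families can
#' predate the ingroup). Below the gain, each branch loses the family with
#' the configured per-branch loss probability; once lost it never
#' reappears (Dollo constraint). Families with zero surviving species are
#' discarded and regenerated, up to a bounded number of attempts.
#'
#' @param config A [synth_config()].
#' @param species_tree Rooted `phylo` (default: [simulate_species_tree()]).
#' @return List: `fm` (a [family_matrix()]), `truth` (data.frame
#'   `family`, `gain_node`, `n_losses` plus list-column-free
#'   `loss_branches` in `truth_losses`), `tree`.
#' @export
simulate_family_evolution <- function(config,
                                      species_tree = simulate_species_tree(config)) {
  loss <- config$gain_loss_rates[2]
  idx <- tree_index(species_tree)
  children <- lapply(seq_len(idx$nnode), function(v) which(idx$parent == v))
  with_seed(derive_seed(config$seed, "families"), {
    gene_counter <- setNames(rep(0L, idx$ntip), idx$tips)
    gene_map <- vector("list", config$n_families)
    gains <- integer(config$n_families)
    loss_list <- vector("list", config$n_families)
    for (f in seq_len(config$n_families)) {
      ok <- FALSE
      for (attempt in 1:200) {
        gain <- sample.int(idx$nnode, 1)
        present <- rep(FALSE, idx$nnode)
        present[gain] <- TRUE
        losses <- integer(0)
        # preorder walk below the gain node
        stack <- children[[gain]]
        while (length(stack) > 0) {
          v <- stack[1]; stack <- stack[-1]
          if (!present[idx$parent[v]]) next
          if (runif(1) < loss) {
            losses <- c(losses, v)
          } else {
            present[v] <- TRUE
            stack <- c(stack, children[[v]])
          }
        }
        tips_present <- which(present[seq_len(idx$ntip)])
        if (length(tips_present) > 0) { ok <- TRUE; break }
      }
      if (!ok)
        stop("family regeneration exhausted after 200 attempts ",
             "(loss rate too high for this tree)")
      gains[f] <- gain
      loss_list[[f]] <- losses
      fam_genes <- setNames(vector("list", idx$ntip), idx$tips)
      for (tp in seq_len(idx$ntip)) {
        if (tp %in% tips_present) {
          n_genes <- 1L + rbinom(1, 1, 0.3)
          ids <- paste0(idx$tips[tp], "_g",
                        gene_counter[tp] + seq_len(n_genes))
          gene_counter[tp] <- gene_counter[tp] + n_genes
          fam_genes[[tp]] <- ids
        } else fam_genes[[tp]] <- character(0)
      }
      gene_map[[f]] <- fam_genes
    }
    names(gene_map) <- sprintf("OG%04d", seq_len(config$n_families))
    fm <- family_matrix(gene_map)
    truth <- data.frame(family = names(gene_map), gain_node = gains,
                        n_losses = lengths(loss_list),
                        stringsAsFactors = FALSE)
    list(fm = fm, truth = truth, truth_losses = setNames(loss_list, names(gene_map)),
         tree = species_tree)
  })
}

#' Simulate a proteome with planted crTP-like signatures
#'
#' Background proteins are i.i.d. draws from the amino-acid background.
#' Planted proteins carry a noisy copy of a common crTP profile after a
#' short (0-49 residue) prefix, followed by a mature tail longer than 250
#' residues. Decoy proteins carry the same block but violate exactly one
#' positional filter: `late_start` decoys start the block after residue
#' 50, `short_mature` decoys have a mature tail of at most 250 residues.
#' Seed crTPs (noisy copies of the profile consensus) stand in for
#' validated crTPs from a related species.
#'
#' @param config A [synth_config()].
#' @return List: `proteome` (named character), `seed_crtps`, `consensus`,
#'   `truth` (list with `planted` data.frame `id`,`start`,`end` and
#'   `decoys` data.frame `id`,`type`,`expected_reason`).
#' @export
simulate_proteome <- function(config) {
  with_seed(derive_seed(config$seed, "proteome"), {
    L <- config$crtp_length
    consensus <- random_aa(L)
    seed_crtps <- setNames(
      vapply(seq_len(config$n_seed_crtps), function(i)
        mutate_seq(consensus, config$crtp_noise), ""),
      paste0("crtp_val", seq_len(config$n_seed_crtps)))
    n_bg <- config$n_proteins - config$n_planted_crtp - config$n_decoy_crtp
    ids <- sprintf("p%04d", seq_len(config$n_proteins))
    roles <- sample(c(rep("planted", config$n_planted_crtp),
                      rep("decoy", config$n_decoy_crtp),
                      rep("background", n_bg)))
    proteome <- character(config$n_proteins)
    planted <- list(); decoys <- list()
    decoy_type <- rep(c("late_start", "short_mature"),
                      length.out = config$n_decoy_crtp)
    d <- 0L
    for (i in seq_len(config$n_proteins)) {
      if (roles[i] == "background") {
        proteome[i] <- random_aa(sample(300:700, 1))
      } else if (roles[i] == "planted") {
        prefix <- sample(0:49, 1)
        tail_len <- sample(260:400, 1)
        proteome[i] <- paste0(random_aa(prefix),
                              mutate_seq(consensus, config$crtp_noise),
                              random_aa(tail_len))
        planted[[length(planted) + 1]] <-
          data.frame(id = ids[i], start = prefix, end = prefix + L,
                     stringsAsFactors = FALSE)
      } else {
        d <- d + 1L
        type <- decoy_type[d]
        if (type == "late_start") {
          prefix <- sample(55:120, 1); tail_len <- sample(260:400, 1)
          reason <- "start"
        } else {
          prefix <- sample(0:49, 1); tail_len <- sample(60:200, 1)
          reason <- "mature"
        }
        proteome[i] <- paste0(random_aa(prefix),
                              mutate_seq(consensus, config$crtp_noise),
                              random_aa(tail_len))
        decoys[[length(decoys) + 1]] <-
          data.frame(id = ids[i], type = type, expected_reason = reason,
                     start = prefix, stringsAsFactors = FALSE)
      }
    }
    names(proteome) <- ids
    list(proteome = proteome, seed_crtps = seed_crtps,
         consensus = consensus,
         truth = list(planted = do.call(rbind, planted) %||%
                        data.frame(id = character(), start = integer(),
                                   end = integer()),
                      decoys = do.call(rbind, decoys) %||%
                        data.frame(id = character(), type = character(),
                                   expected_reason = character(),
                                   start = integer())))
  })
}

#' Simulate a replicated diurnal expression time course
#'
#' Rhythmic genes follow `baseline * (1 + a * cos(2*pi*(t - phase)/24))`
#' with the phase drawn from the sampled timepoints and relative amplitude
#' `a = noise_cv * amplitude_over_sigma`, so that the planted amplitude is
#' `amplitude_over_sigma` noise standard deviations. Non-rhythmic genes
#' are flat. Replicate noise is lognormal multiplicative with coefficient
#' of variation `noise_cv`; values are rounded to integer counts.
#'
#' @param config A [synth_config()].
#' @return List: `values` (genes x samples), `samples` metadata
#'   data.frame, `truth` (data.frame `gene_id`, `rhythmic`, `phase_h`).
#' @export
simulate_timecourse <- function(config) {
  a <- config$noise_cv * config$amplitude_over_sigma
  if (a > 1)
    stop("amplitude_over_sigma x noise_cv exceeds 1: negative means")
  with_seed(derive_seed(config$seed, "timecourse"), {
    n <- config$n_genes_expr
    n_r <- if (a > 0) round(config$frac_rhythmic * n) else 0L
    genes <- sprintf("g%05d", seq_len(n))
    rhythmic <- seq_len(n) <= n_r
    phase <- ifelse(rhythmic,
                    sample(config$timepoints_h, n, replace = TRUE),
                    NA_real_)
    samples <- expand.grid(replicate = seq_len(config$n_replicates),
                           timepoint_h = config$timepoints_h)
    samples <- data.frame(condition = "ctrl",
                          timepoint_h = samples$timepoint_h,
                          replicate = samples$replicate,
                          stringsAsFactors = FALSE)
    baseline <- exp(rnorm(n, log(300), 0.5))
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    vals <- matrix(0, n, nrow(samples),
                   dimnames = list(genes, sprintf("ctrl_t%g_r%d",
                                                  samples$timepoint_h,
                                                  samples$replicate)))
    for (i in seq_len(n)) {
      mu <- if (rhythmic[i])
        baseline[i] * (1 + a * cos(2 * pi * (samples$timepoint_h - phase[i]) / 24))
      else rep(baseline[i], nrow(samples))
      vals[i, ] <- round(mu * exp(rnorm(nrow(samples), 0, sdlog)))
    }
    list(values = vals, samples = samples,
         truth = data.frame(gene_id = genes, rhythmic = rhythmic,
                            phase_h = phase, stringsAsFactors = FALSE))
  })
}

# -- gene-tree construction helpers -----------------------------------------

# Random binary newick of the given leaf labels with supports drawn from
# `sup_range`; returns the string without outer parentheses handling.
nwk_clade <- function(labels, sup_range = c(85, 100)) {
  if (length(labels) == 1) return(labels)
  k <- sample(seq_len(length(labels) - 1), 1)
  part <- sample(labels)
  left <- nwk_clade(part[1:k], sup_range)
  right <- nwk_clade(part[(k + 1):length(part)], sup_range)
  sup <- sample(sup_range[1]:sup_range[2], 1)
  paste0("(", left, ",", right, ")", sup)
}

#' Simulate gene trees with planted HGT/EGT signal
#'
#' HGT-true trees nest a query (focal Paulinella) leaf inside an
#' exclusively bacterial clade with support 100; EGT-true trees nest it
#' among alpha-cyanobacteria; negative trees place the query among
#' eukaryotes with an unrelated supported bacterial clade elsewhere.
#' Filter-fodder trees deliberately violate one discard rule (too few
#' leaves, too few bacterial taxa, or polyphyletic Paulinella). Leaf
#' labels encode taxonomy by prefix (`QRY_`, `PAU_`, `BAC_`, `CYA_`,
#' `ACY_`, `EUK_`).
#'
#' @param config A [synth_config()].
#' @return List: `trees` (named list of `phylo`), `groups` (label ->
#'   group map), `truth` (data.frame `tree_id`, `class`,
#'   `expected_verdict`, `discard_reason`).
#' @export
simulate_gene_trees <- function(config) {
  n <- config$n_gene_trees
  n_hgt <- round(config$frac_hgt * n)
  n_egt <- round(config$frac_egt * n)
  n_fodder <- round(config$frac_fodder * n)
  n_neg <- n - n_hgt - n_egt - n_fodder
  stopifnot(n_neg >= 0)
  with_seed(derive_seed(config$seed, "gene_trees"), {
    mk_labels <- function(prefix, k, tid)
      if (k > 0) sprintf("%s_%s_%d", prefix, tid, seq_len(k)) else character(0)
    build <- function(tid, class) {
      if (class == "HGT") {
        bac_in <- mk_labels("BAC", sample(5:8, 1), tid)
        bac_out <- mk_labels("BACX", sample(0:1, 1), tid)
        n_euk <- max(sample(4:6, 1),
                     10 - (1 + length(bac_in) + length(bac_out)))
        euk <- mk_labels("EUK", n_euk, tid)
        core <- paste0("(", nwk_clade(c(paste0("QRY_", tid), bac_in),
                                      c(95, 100)), ",",
                       nwk_clade(euk, c(70, 100)),
                       if (length(bac_out) > 0)
                         paste0(",", paste(bac_out, collapse = ",")) else "",
                       ");")
        list(nwk = core, verdict = "HGT", reason = NA_character_)
      } else if (class == "EGT") {
        acy <- mk_labels("ACY", sample(4:6, 1), tid)
        cya_out <- mk_labels("CYA", sample(0:1, 1), tid)
        bac <- mk_labels("BAC", sample(2:3, 1), tid)
        n_euk <- max(sample(3:5, 1),
                     10 - (1 + length(acy) + length(cya_out) + length(bac)))
        euk <- mk_labels("EUK", n_euk, tid)
        core <- paste0("(", nwk_clade(c(paste0("QRY_", tid), acy),
                                      c(95, 100)), ",",
                       nwk_clade(c(euk, bac), c(70, 100)),
                       if (length(cya_out) > 0)
                         paste0(",", paste(cya_out, collapse = ",")) else "",
                       ");")
        list(nwk = core, verdict = "EGT", reason = NA_character_)
      } else if (class == "negative") {
        euk <- mk_labels("EUK", sample(4:6, 1), tid)
        bac <- mk_labels("BAC", sample(5:7, 1), tid)
        # nest the query properly inside the eukaryote clade (eukaryotes
        # on both sides), so no unrooted split groups it with bacteria
        k <- sample(seq_len(length(euk) - 1), 1)
        inner <- nwk_clade(c(paste0("QRY_", tid), euk[1:k]), c(80, 100))
        outer <- nwk_clade(euk[(k + 1):length(euk)], c(80, 100))
        core <- paste0("((", inner, ",", outer, ")",
                       sample(80:100, 1), ",",
                       nwk_clade(bac, c(95, 100)), ");")
        list(nwk = core, verdict = "negative", reason = NA_character_)
      } else {
        type <- sample(c("small", "fewbac", "polyphyly"), 1)
        if (type == "small") {
          euk <- mk_labels("EUK", 3, tid)
          bac <- mk_labels("BAC", 4, tid)
          core <- paste0("(",
                         nwk_clade(c(paste0("QRY_", tid), euk), c(80, 100)),
                         ",", nwk_clade(bac, c(95, 100)), ");")
          list(nwk = core, verdict = "discarded", reason = "leaves<10")
        } else if (type == "fewbac") {
          euk <- mk_labels("EUK", 7, tid)
          bac <- mk_labels("BAC", 4, tid)
          core <- paste0("(",
                         nwk_clade(c(paste0("QRY_", tid), euk), c(80, 100)),
                         ",", nwk_clade(bac, c(95, 100)), ");")
          list(nwk = core, verdict = "discarded", reason = "bacteria<5")
        } else {
          euk <- mk_labels("EUK", 4, tid)
          bac <- mk_labels("BAC", 6, tid)
          core <- paste0("(",
                         nwk_clade(c(paste0("QRY_", tid), euk), c(80, 100)),
                         ",",
                         nwk_clade(c(paste0("PAU_", tid), bac), c(95, 100)),
                         ");")
          list(nwk = core, verdict = "discarded",
               reason = "paulinella_polyphyly")
        }
      }
    }
    classes <- sample(c(rep("HGT", n_hgt), rep("EGT", n_egt),
                        rep("negative", n_neg), rep("fodder", n_fodder)))
    trees <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      tid <- sprintf("t%03d", i)
      b <- build(tid, classes[i])
      trees[[i]] <- read_newick_text(b$nwk)
      truth[[i]] <- data.frame(tree_id = tid, class = classes[i],
                               expected_verdict = b$verdict,
                               discard_reason = b$reason,
                               stringsAsFactors = FALSE)
    }
    names(trees) <- sprintf("t%03d", seq_len(n))
    all_labels <- unique(unlist(lapply(trees, `[[`, "tip.label")))
    groups <- make_taxon_groups(all_labels,
                                c(QRY = "query", PAU = "other_paulinella",
                                  ACY = "alpha_cyanobacteria",
                                  CYA = "cyanobacteria", BAC = "bacteria",
                                  EUK = "eukarya", ARC = "archaea"))
    list(trees = trees, groups = groups,
         truth = do.call(rbind, truth))
  })
}

#' Simulate labeled genome regions and aligned reads
#'
#' The genome (one contig) is partitioned into alternating non-viral and
#' viral blocks (10 of each). Read starts are placed uniformly within
#' each block at a Poisson-distributed count matching the class's expected
#' fold coverage, so the expected breadth of coverage per class is
#' approximately `1 - exp(-depth)` (recorded in the truth).
#'
#' @param config A [synth_config()].
#' @return List: `regions`, `alignments` (interval data.frames), `truth`
#'   (list `expected_breadth`, `depths`).
#' @export
simulate_regions_and_reads <- function(config) {
  with_seed(derive_seed(config$seed, "regions"), {
    nb <- 10L
    v_len <- round(config$genome_len * config$frac_viral / nb)
    n_len <- round(config$genome_len * (1 - config$frac_viral) / nb)
    stopifnot(v_len > config$read_len, n_len > config$read_len)
    regions <- list(); alignments <- list()
    pos <- 0L
    for (b in seq_len(nb)) {
      for (cls in c("nonviral", "viral")) {
        len <- if (cls == "viral") v_len else n_len
        depth <- if (cls == "viral") config$read_depth_viral
                 else config$read_depth_nonviral
        regions[[length(regions) + 1]] <-
          data.frame(contig = "chr1", start = pos, end = pos + len,
                     label = cls, stringsAsFactors = FALSE)
        n_reads <- rpois(1, depth * len / config$read_len)
        if (n_reads > 0) {
          starts <- pos + sample.int(len - config$read_len + 1, n_reads,
                                     replace = TRUE) - 1L
          alignments[[length(alignments) + 1]] <-
            data.frame(contig = "chr1", start = starts,
                       end = starts + config$read_len,
                       label = sprintf("read_%s_%d_%d", cls, b,
                                       seq_len(n_reads)),
                       stringsAsFactors = FALSE)
        }
        pos <- pos + len
      }
    }
    list(regions = do.call(rbind, regions),
         alignments = do.call(rbind, alignments) %||%
           data.frame(contig = character(), start = integer(),
                      end = integer(), label = character()),
         truth = list(expected_breadth = c(
           viral = 1 - exp(-config$read_depth_viral),
           nonviral = 1 - exp(-config$read_depth_nonviral)),
           depths = c(viral = config$read_depth_viral,
                      nonviral = config$read_depth_nonviral)))
  })
}

#' Write the full synthetic input bundle to a directory
#'
#' Produces every file the pipeline consumes (proteome.faa, seeds.faa,
#' ogf.tsv, species_tree.nwk, gene_trees/*.nwk, counts.tsv, regions.bed,
#' alignments.bed) plus truth.json with the generative ground truth.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of simulated objects.
#' @export
simulate_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "gene_trees"), showWarnings = FALSE)
  fam <- simulate_family_evolution(config)
  prot <- simulate_proteome(config)
  tc <- simulate_timecourse(config)
  gt <- simulate_gene_trees(config)
  rr <- simulate_regions_and_reads(config)
  write_fasta(prot$proteome, file.path(dir, "proteome.faa"))
  write_fasta(prot$seed_crtps, file.path(dir, "seeds.faa"))
  write_ogf_table(fam$fm, file.path(dir, "ogf.tsv"))
  write_newick(fam$tree, file.path(dir, "species_tree.nwk"))
  for (id in names(gt$trees))
    write_newick(gt$trees[[id]], file.path(dir, "gene_trees",
                                           paste0(id, ".nwk")))
  write_counts(tc$values, tc$samples, file.path(dir, "counts.tsv"))
  write_bed(rr$regions, file.path(dir, "regions.bed"))
  write_bed(rr$alignments, file.path(dir, "alignments.bed"))
  truth <- list(families = fam$truth, proteome = prot$truth,
                timecourse = tc$truth, gene_trees = gt$truth,
                coverage = rr$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(config = config, families = fam, proteome = prot,
                 timecourse = tc, gene_trees = gt, regions = rr))
}
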