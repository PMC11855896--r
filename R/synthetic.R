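# Class set-point tables used as generator defaults. Residue targets are the
# published per-class median compositions of mosquito CYP proteins; genomic
# targets are the per-class median gene-structure values. Declared null
# features get identical targets in both classes (see cohort_config).

#' @noRd
default_composition_targets <- function() {
  # class medians of per-residue percentages; medians do not sum to exactly
  # 100 (99.37 / 99.46), so each row is rescaled proportionally to sum 100
  m <- rbind(
    stable = c(A = 6.1100, C = 1.5238, D = 5.3465, E = 6.1151, F = 6.2000,
               G = 5.3254, H = 2.3301, I = 6.0827, K = 5.4000, L = 11.0656,
               M = 2.9851, N = 3.9448, P = 5.1081, Q = 3.5849, R = 6.6202,
               S = 5.4104, T = 5.2104, V = 6.2745, W = 1.1236, Y = 3.6072),
    labile = c(A = 5.6711, C = 1.1811, D = 5.4409, E = 6.4338, F = 6.5476,
               G = 5.6075, H = 2.1696, I = 6.1185, K = 6.4639, L = 10.0616,
               M = 3.3730, N = 4.0161, P = 5.0710, Q = 3.4765, R = 6.0852,
               S = 5.3435, T = 5.4326, V = 6.5056, W = 0.9452, Y = 3.5185)
  )
  100 * m / rowSums(m)
}

#' @noRd
default_genomic_targets <- function() {
  list(
    stable = list(exon_count = 4L, exon_total = 1518, intron_total = 612,
                  gc = 44.78),
    labile = list(exon_count = 3L, exon_total = 1524, intron_total = 311,
                  gc = 47.20)
  )
}

#' @noRd
default_term_proportions <- function() {
  data.frame(
    term_id = c("GO:0048856", "GO:0008610", "GO:0006805", "GO:0046680"),
    description = c("anatomical structure development",
                    "lipid biosynthetic process",
                    "xenobiotic metabolic process",
                    "response to DDT"),
    stable = c(0.551, 0.575, 0.098, 0.122),
    labile = c(0.311, 0.099, 0.286, 0.357),
    stringsAsFactors = FALSE
  )
}

# Fully conserved haem window of the labile class (pattern span 11 plus the
# 4 trailing profiled columns).
HAEM_CONSENSUS <- "PFSAGPRNCIGQRFA"

# Fractional N-to-C placement of the five signature motifs along a sequence.
MOTIF_OFFSETS <- c(helixC = 0.10, helixI = 0.38, helixK = 0.55,
                   PERF = 0.78, haem = 0.88)

#' Configuration of a synthetic CYP cohort
#'
#' Builds a validated generator configuration. Defaults encode the study
#' conditions: per-class residue compositions and gene-structure medians at
#' the published mosquito CYP class set-points, 50 genes per class over four
#' species, a fixed haem consensus in the labile class versus
#' pattern-sampled haem windows in the stable class, and annotation-term
#' proportions with class contrasts. Declared null features (by default the
#' transcript count and residues Ile, Ser, Tyr) are forced to identical
#' targets in both classes, with the remaining composition renormalised per
#' class so each vector sums to 100.
#'
#' @param seed integer seed; the entire cohort is a deterministic function
#'   of the configuration including this seed.
#' @param n_species number of species labels to cycle through.
#' @param genes_per_class named vector `c(stable =, labile =)` of gene counts.
#' @param length_mean,length_cv protein length distribution (residues;
#'   lognormal with this mean and coefficient of variation).
#' @param composition stable/labile residue target matrix (percent rows
#'   summing to 100 before null-feature equalisation); default the built-in
#'   set-points.
#' @param genomic per-class gene-structure targets (list as in the default:
#'   `exon_count` median, `exon_total`, `intron_total` bp, `gc` percent).
#' @param cv coefficient of variation applied to each drawn length quantity
#'   (per-exon and per-intron lengths).
#' @param gc_sd per-gene GC standard deviation in percentage points.
#' @param haem_policy named character: `"fixed_consensus"` or
#'   `"pattern_sampled"` per class.
#' @param term_proportions data.frame `term_id`, `description`, `stable`,
#'   `labile` (per-class annotation probabilities).
#' @param null_features feature names designed to carry no class difference.
#' @param composition_noise `"matched"` (default: per-protein composition
#'   planted at the class target by randomized largest-remainder allocation)
#'   or `"multinomial"` (i.i.d. background draws).
#' @param multi_transcript_rate fraction of genes given a second, shorter
#'   transcript (exercises the longest-transcript rule; default 0).
#' @param null_cohort if `TRUE`, both classes share the averaged targets
#'   (no planted effect anywhere) — used for type-I error studies.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_species = 4L,
                          genes_per_class = c(stable = 50L, labile = 50L),
                          length_mean = 520, length_cv = 0.3,
                          composition = default_composition_targets(),
                          genomic = default_genomic_targets(),
                          cv = 0.3, gc_sd = 6,
                          haem_policy = c(stable = "pattern_sampled",
                                          labile = "fixed_consensus"),
                          term_proportions = default_term_proportions(),
                          null_features = c("n_transcripts", "I", "S", "Y"),
                          composition_noise = c("matched", "multinomial"),
                          multi_transcript_rate = 0,
                          null_cohort = FALSE) {
  composition_noise <- match.arg(composition_noise)
  stopifnot(all(c("stable", "labile") %in% rownames(composition)),
            all(AA20 %in% colnames(composition)),
            all(genes_per_class >= 1), n_species >= 1)
  composition <- composition[c("stable", "labile"), AA20]
  for (cl in c("stable", "labile")) {
    if (abs(sum(composition[cl, ]) - 100) > 1e-6) {
      stop(sprintf("'%s' composition does not sum to 100", cl), call. = FALSE)
    }
  }
  if (null_cohort) {
    avg <- colMeans(composition)
    composition["stable", ] <- avg
    composition["labile", ] <- avg
    g_avg <- list(exon_count = 3L,
                  exon_total = mean(c(genomic$stable$exon_total,
                                      genomic$labile$exon_total)),
                  intron_total = mean(c(genomic$stable$intron_total,
                                        genomic$labile$intron_total)),
                  gc = mean(c(genomic$stable$gc, genomic$labile$gc)))
    genomic <- list(stable = g_avg, labile = g_avg)
    term_proportions$stable <- term_proportions$labile <-
      (term_proportions$stable + term_proportions$labile) / 2
  } else {
    # equalise declared null residues across classes, renormalise the rest
    null_res <- intersect(null_features, AA20)
    if (length(null_res)) {
      eq <- colMeans(composition[, null_res, drop = FALSE])
      other <- setdiff(AA20, null_res)
      for (cl in c("stable", "labile")) {
        composition[cl, null_res] <- eq
        composition[cl, other] <- composition[cl, other] *
          (100 - sum(eq)) / sum(composition[cl, other])
      }
    }
  }
  for (cl in c("stable", "labile")) {
    stopifnot(abs(sum(composition[cl, ]) - 100) < 1e-9)
  }
  structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    genes_per_class = genes_per_class,
    length_mean = length_mean, length_cv = length_cv,
    composition = composition, genomic = genomic, cv = cv, gc_sd = gc_sd,
    haem_policy = haem_policy, term_proportions = term_proportions,
    null_features = null_features, composition_noise = composition_noise,
    multi_transcript_rate = multi_transcript_rate,
    null_cohort = null_cohort
  ), class = "cohort_config")
}

# Randomized largest-remainder allocation of `total` items over categories
# with target weights p: expectation is exact, residual is < 1 item.
#' @noRd
alloc_counts <- function(total, p) {
  p <- p / sum(p)
  expect <- total * p
  base <- floor(expect)
  k <- total - sum(base)
  if (k > 0) {
    rem <- expect - base + 1e-12
    extra <- sample(seq_along(p), k, replace = FALSE, prob = rem)
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

#' @noRd
realise_motif <- function(motif, policy, composition) {
  if (motif$name == "haem" && policy == "fixed_consensus") {
    return(HAEM_CONSENSUS)
  }
  comp <- composition[AA20] / 100
  draw_bg <- function(n) sample(AA20, n, replace = TRUE, prob = comp)
  chars <- vapply(motif$pattern, function(p) {
    if (identical(p, "x")) draw_bg(1L)
    else if (length(p) == 1L) p
    else sample(p, 1L)
  }, character(1))
  trailing <- motif$window - motif$span
  if (trailing > 0L) chars <- c(chars, draw_bg(trailing))
  paste(chars, collapse = "")
}

#' Sample a protein sequence with planted motif windows
#'
#' Generates a sequence of the requested length whose residue composition
#' follows the target vector and which contains each supplied motif window
#' verbatim at a fixed fractional offset (N-to-C, non-overlapping). In the
#' default `"matched"` mode the total residue counts are allocated from the
#' target by randomized largest-remainder rounding and the motif residues
#' are deducted from that allocation, so the final composition tracks the
#' target irrespective of motif policy; in `"multinomial"` mode background
#' residues are drawn i.i.d. from the target.
#'
#' @param composition named percent vector over the 20 standard residues
#'   (sums to 100).
#' @param length sequence length in residues; must accommodate the motif
#'   windows at their offsets.
#' @param motifs named character vector of realised motif windows (possibly
#'   empty); names select the fractional offsets.
#' @param offsets named fractional offsets in (0, 1) (defaults to the
#'   built-in five-motif layout).
#' @param noise `"matched"` or `"multinomial"`.
#' @return A character scalar sequence of the requested length.
#' @export
sample_protein <- function(composition, length, motifs = character(0),
                           offsets = MOTIF_OFFSETS,
                           noise = c("matched", "multinomial")) {
  noise <- match.arg(noise)
  if (abs(sum(composition[AA20]) - 100) > 1e-6) {
    stop("composition does not sum to 100", call. = FALSE)
  }
  comp <- composition[AA20]
  length <- as.integer(length)
  placements <- NULL
  if (base::length(motifs)) {
    if (is.null(names(motifs)) || !all(names(motifs) %in% names(offsets))) {
      stop("motifs must be named and have matching offsets", call. = FALSE)
    }
    ord <- order(offsets[names(motifs)])
    motifs <- motifs[ord]
    starts <- pmax(1L, as.integer(floor(offsets[names(motifs)] * length)) + 1L)
    ends <- starts + nchar(motifs) - 1L
    if (any(ends > length) || any(utils::head(ends, -1L) >= utils::tail(starts, -1L))) {
      stop("sequence too short to place the motif windows", call. = FALSE)
    }
    placements <- data.frame(start = starts, end = ends,
                             window = unname(motifs), stringsAsFactors = FALSE)
  }
  motif_chars <- if (is.null(placements)) character(0)
                 else unlist(strsplit(placements$window, "", fixed = TRUE))
  l_bg <- length - base::length(motif_chars)
  if (l_bg < 0L) stop("sequence too short to place the motif windows", call. = FALSE)
  if (noise == "matched") {
    total <- alloc_counts(length, comp)
    used <- table(factor(motif_chars, levels = AA20))
    bg <- as.integer(total) - as.integer(used)
    names(bg) <- AA20
    if (any(bg < 0L)) bg[bg < 0L] <- 0L
    gap <- l_bg - sum(bg)
    if (gap > 0L) {
      add <- alloc_counts(gap, comp)
      bg <- bg + add
    } else if (gap < 0L) {
      for (i in seq_len(-gap)) {
        j <- which.max(bg)
        bg[j] <- bg[j] - 1L
      }
    }
  } else {
    bg <- stats::setNames(as.integer(stats::rmultinom(1L, l_bg, comp / 100)), AA20)
  }
  pool <- sample(rep(AA20, times = bg))
  out <- character(length)
  if (!is.null(placements)) {
    for (i in seq_len(nrow(placements))) {
      out[placements$start[i]:placements$end[i]] <-
        strsplit(placements$window[i], "", fixed = TRUE)[[1L]]
    }
  }
  out[out == ""] <- pool
  paste(out, collapse = "")
}

#' Sample one gene model and its genomic sequence
#'
#' Builds an exon/intron structure (exon1, intron1, exon2, ...) whose gene
#' length is exactly the sum of the exon and intron lengths, plus an i.i.d.
#' nucleotide sequence at the requested GC fraction.
#'
#' @param exon_count number of exons (>= 1).
#' @param exon_lengths integer vector of exon lengths (bp), length
#'   `exon_count`.
#' @param intron_lengths integer vector of intron lengths (bp), length
#'   `exon_count - 1`.
#' @param gc GC fraction in (0, 1) for the emitted sequence.
#' @return List with `gene_length`, `exons` (matrix of `start`, `end`,
#'   1-based inclusive), and `sequence`.
#' @export
sample_gene_model <- function(exon_count, exon_lengths, intron_lengths, gc) {
  exon_count <- as.integer(exon_count)
  stopifnot(exon_count >= 1L, length(exon_lengths) == exon_count,
            length(intron_lengths) == exon_count - 1L,
            gc > 0, gc < 1)
  if (any(exon_lengths <= 0) || any(intron_lengths < 0)) {
    stop("exon lengths must be positive and intron lengths non-negative",
         call. = FALSE)
  }
  starts <- integer(exon_count); ends <- integer(exon_count)
  pos <- 1L
  for (i in seq_len(exon_count)) {
    starts[i] <- pos
    ends[i] <- pos + as.integer(exon_lengths[i]) - 1L
    pos <- ends[i] + 1L
    if (i < exon_count) pos <- pos + as.integer(intron_lengths[i])
  }
  gene_length <- ends[exon_count]
  bases <- sample(c("G", "C", "A", "T"), gene_length, replace = TRUE,
                  prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
  list(gene_length = gene_length,
       exons = cbind(start = starts, end = ends),
       sequence = paste(bases, collapse = ""))
}

#' @noRd
rlnorm_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Split an integer total into k pieces of at least min_len bp, with
# moderately even random proportions; the pieces sum to the total exactly.
#' @noRd
split_lengths <- function(total, k, min_len) {
  total <- as.integer(round(total))
  k <- as.integer(k)
  if (k == 1L) return(max(total, min_len))
  total <- max(total, k * min_len)
  w <- stats::rgamma(k, shape = 8)
  extra <- total - k * min_len
  alloc <- as.integer(floor(extra * w / sum(w)))
  rem <- extra - sum(alloc)
  if (rem > 0L) {
    idx <- sample.int(k, rem)
    alloc[idx] <- alloc[idx] + 1L
  }
  min_len + alloc
}

#' Generate a synthetic stable/labile CYP cohort
#'
#' Emits a complete analysis input bundle: protein FASTA, per-gene genomic
#' contig FASTA, GFF3 gene models, an ortholog-group table encoding the
#' class structure (stable genes sit in cross-species groups with at most
#' three same-species paralogs; labile genes sit in single-species expansion
#' groups of five or more), an annotation table, and the truth labels. All
#' randomness derives from the configuration seed; the same configuration
#' produces byte-identical files.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the file `paths`, the `truth` data.frame
#'   (`gene_id`, `class`, `species`), and the `config`.
#' @export
generate_cohort <- function(config, out_dir = tempfile("cohort")) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(config$seed, {
    motifs <- p450_motifs()
    species_pool <- paste0("sp", seq_len(config$n_species))
    genes <- list(); proteins <- character(0); contigs <- character(0)
    gff <- c("##gff-version 3")
    ortho <- list(); truth <- list()

    for (cl in c("stable", "labile")) {
      n_genes <- as.integer(config$genes_per_class[[cl]])
      prefix <- if (cl == "stable") "STB" else "LAB"
      ids <- sprintf("%s%04d", prefix, seq_len(n_genes))

      # --- species assignment and ortholog groups -------------------------
      if (cl == "stable") {
        species <- rep_len(species_pool, n_genes)
        # cross-species groups; per-species family size <= 4 (k <= 3)
        remaining <- split(ids, species)
        gcount <- 0L
        while (any(lengths(remaining) > 0)) {
          gcount <- gcount + 1L
          gid <- sprintf("OG_S%03d", gcount)
          for (sp in names(remaining)) {
            if (!length(remaining[[sp]])) next
            fam <- sample(1:4, 1L, prob = c(0.6, 0.3, 0.08, 0.02))
            take <- utils::head(remaining[[sp]], fam)
            remaining[[sp]] <- setdiff(remaining[[sp]], take)
            if (length(take)) {
              ortho[[length(ortho) + 1L]] <- data.frame(
                group_id = gid, species = sp, gene_id = take,
                stringsAsFactors = FALSE)
            }
          }
        }
      } else {
        # single-species expansion groups of >= 5 members (k >= 4)
        if (n_genes < 5L) {
          stop("labile class needs at least 5 genes to satisfy the >= 4 paralog rule",
               call. = FALSE)
        }
        species <- character(n_genes)
        left <- ids; gcount <- 0L; sp_i <- 0L
        while (length(left)) {
          gcount <- gcount + 1L
          sp_i <- sp_i %% config$n_species + 1L
          fam <- sample(5:8, 1L)
          if (length(left) - fam < 5L) fam <- length(left)
          take <- utils::head(left, fam)
          left <- setdiff(left, take)
          sp <- species_pool[sp_i]
          species[match(take, ids)] <- sp
          ortho[[length(ortho) + 1L]] <- data.frame(
            group_id = sprintf("OG_L%03d", gcount), species = sp,
            gene_id = take, stringsAsFactors = FALSE)
        }
      }
      truth[[cl]] <- data.frame(gene_id = ids, class = cl, species = species,
                                stringsAsFactors = FALSE)

      comp <- config$composition[cl, ]
      gpar <- config$genomic[[cl]]

      for (i in seq_len(n_genes)) {
        gid <- ids[i]
        # --- protein -----------------------------------------------------
        L <- max(130L, as.integer(round(rlnorm_cv(1L, config$length_mean,
                                                  config$length_cv))))
        wins <- vapply(motifs, function(m) {
          pol <- if (m$name == "haem") config$haem_policy[[cl]] else "pattern_sampled"
          realise_motif(m, pol, comp)
        }, character(1))
        proteins[gid] <- sample_protein(comp, L, wins,
                                        noise = config$composition_noise)
        # --- gene model --------------------------------------------------
        n_exon <- max(1L, gpar$exon_count +
                        sample(c(-1L, 0L, 1L), 1L, prob = c(0.25, 0.5, 0.25)))
        # totals drawn directly with the CV of a sum of per-piece CV-0.3
        # draws, then split; keeps gene length decoupled from count jitter
        exon_total_i <- rlnorm_cv(1L, gpar$exon_total,
                                  config$cv / sqrt(gpar$exon_count))
        exons <- split_lengths(exon_total_i, n_exon, min_len = 30L)
        introns <- if (n_exon > 1L) {
          intron_total_i <- rlnorm_cv(1L, gpar$intron_total,
                                      config$cv / sqrt(max(1L, gpar$exon_count - 1L)))
          split_lengths(intron_total_i, n_exon - 1L, min_len = 40L)
        } else integer(0)
        gc_gene <- min(70, max(25, stats::rnorm(1L, gpar$gc, config$gc_sd))) / 100
        model <- sample_gene_model(n_exon, exons, introns, gc_gene)
        ctg <- paste0("ctg_", gid)
        contigs[ctg] <- model$sequence
        tx1 <- paste0(gid, ".t1")
        gff <- c(gff,
          sprintf("%s\tcypstab\tgene\t1\t%d\t.\t+\t.\tID=%s", ctg,
                  model$gene_length, gid),
          sprintf("%s\tcypstab\tmRNA\t1\t%d\t.\t+\t.\tID=%s;Parent=%s", ctg,
                  model$gene_length, tx1, gid),
          sprintf("%s\tcypstab\texon\t%d\t%d\t.\t+\t.\tID=%s.e%d;Parent=%s",
                  ctg, model$exons[, "start"], model$exons[, "end"],
                  tx1, seq_len(n_exon), tx1))
        if (config$multi_transcript_rate > 0 && n_exon >= 2L &&
            stats::runif(1L) < config$multi_transcript_rate) {
          tx2 <- paste0(gid, ".t2")
          keep <- seq_len(n_exon - 1L)   # shorter: drops the last exon
          gff <- c(gff,
            sprintf("%s\tcypstab\tmRNA\t1\t%d\t.\t+\t.\tID=%s;Parent=%s", ctg,
                    model$gene_length, tx2, gid),
            sprintf("%s\tcypstab\texon\t%d\t%d\t.\t+\t.\tID=%s.e%d;Parent=%s",
                    ctg, model$exons[keep, "start"], model$exons[keep, "end"],
                    tx2, keep, tx2))
        }
      }
    }

    truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
    ortho <- do.call(rbind, c(ortho, list(make.row.names = FALSE)))

    # --- annotations -----------------------------------------------------
    ann <- list()
    tp <- config$term_proportions
    for (t in seq_len(nrow(tp))) {
      pr <- ifelse(truth$class == "stable", tp$stable[t], tp$labile[t])
      hit <- stats::runif(nrow(truth)) < pr
      if (any(hit)) {
        ann[[length(ann) + 1L]] <- data.frame(
          gene_id = truth$gene_id[hit], term_id = tp$term_id[t],
          description = tp$description[t], stringsAsFactors = FALSE)
      }
    }
    ann <- if (length(ann)) {
      do.call(rbind, c(ann, list(make.row.names = FALSE)))
    } else {
      data.frame(gene_id = character(0), term_id = character(0),
                 description = character(0), stringsAsFactors = FALSE)
    }

    paths <- list(
      proteins = file.path(out_dir, "proteins.fasta"),
      genome = file.path(out_dir, "genome.fasta"),
      gff3 = file.path(out_dir, "genes.gff3"),
      orthologs = file.path(out_dir, "orthologs.tsv"),
      annotations = file.path(out_dir, "annotations.tsv"),
      truth = file.path(out_dir, "truth.tsv")
    )
    Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins),
                                paths$proteins)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs),
                                paths$genome)
    writeLines(gff, paths$gff3)
    utils::write.table(ortho, paths$orthologs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(list(paths = paths, truth = truth, config = config))
  })
}
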