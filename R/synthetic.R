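#' Configuration for the synthetic data generator
#'
#' Defines the miniature study the generator emulates: a multi-chromosome
#' genome with non-overlapping gene models, IP/input ChIP fragment sets with
#' broad enriched domains planted over a Poisson background, and
#' negative-binomial count matrices with planted fold changes. A configurable
#' subset of genes (the true HDEGs) has its expression change anti-coupled to
#' a promoter domain flip; decoy genes violate that coupling in one of the two
#' possible ways (expression change without a domain change, or the reverse).
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_genes number of genes placed on the genome.
#' @param n_stages number of developmental stages (3 for the full pipeline).
#' @param reps_chip ChIP replicates per channel per stage.
#' @param reps_rna RNA replicates per stage.
#' @param bg_rate Poisson background rate, expected fragments per bp.
#' @param domain_fold enrichment multiplier (>= 1) of the IP rate inside a
#'   planted domain that is present at a stage.
#' @param domain_width width in bp of gene-anchored planted domains.
#' @param n_true_hdegs number of genes with anti-coupled expression/domain
#'   changes (the planted HDEGs).
#' @param n_decoys number of decoy genes; half receive an expression change
#'   with no domain change, half a domain change with no expression change.
#' @param lfc_planted log2 fold change planted on DEGs.
#' @param nb_dispersion negative-binomial dispersion alpha (0 gives Poisson).
#' @param frag_len fragment length in bp (fragments are fixed-length
#'   intervals placed by start coordinate; no sequence is simulated).
#' @param frac_lowmapq fraction of fragments given MAPQ < 20.
#' @param dup_frac fraction of fragments duplicated exactly.
#' @param flank promoter half-width in bp used for planting geometry.
#' @param p_silent probability a non-planted gene is silent.
#' @param coupling named probabilities (silent/low/medium/high) that a
#'   non-planted gene carries a constant promoter domain, anti-coupled to its
#'   baseline expression tier; set to zeros for no coupling.
#' @param n_bg_domains number of intergenic background domains (present at
#'   every stage) the generator attempts to place.
#' @param bg_domain_width width in bp of intergenic background domains.
#' @param stage_labels labels for the stages; defaults to d33/d65/d90 when
#'   `n_stages` is 3.
#' @param seed master seed; all outputs draw from labelled substreams of it.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_chroms = 4, chrom_length = 2.5e6, n_genes = 2000,
                         n_stages = 3, reps_chip = 2, reps_rna = 3,
                         bg_rate = 0.02, domain_fold = 8, domain_width = 10000,
                         n_true_hdegs = 100, n_decoys = 100, lfc_planted = 2,
                         nb_dispersion = 0.05, frag_len = 150,
                         frac_lowmapq = 0.05, dup_frac = 0.02, flank = 5000,
                         p_silent = 0.25,
                         coupling = c(silent = 0.7, low = 0.45,
                                      medium = 0.2, high = 0.05),
                         n_bg_domains = 25, bg_domain_width = 5000,
                         stage_labels = NULL, seed = 1) {
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              n_genes = n_genes, n_stages = n_stages, reps_chip = reps_chip,
              reps_rna = reps_rna, bg_rate = bg_rate,
              domain_fold = domain_fold, domain_width = domain_width,
              n_true_hdegs = n_true_hdegs, n_decoys = n_decoys,
              lfc_planted = lfc_planted, nb_dispersion = nb_dispersion,
              frag_len = frag_len, frac_lowmapq = frac_lowmapq,
              dup_frac = dup_frac, flank = flank, p_silent = p_silent,
              coupling = coupling, n_bg_domains = n_bg_domains,
              bg_domain_width = bg_domain_width, seed = seed)
  counts <- c("n_chroms", "n_genes", "n_stages", "reps_chip", "reps_rna",
              "n_true_hdegs", "n_decoys", "n_bg_domains")
  for (f in counts)
    if (cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop("'", f, "' must be a non-negative integer")
  if (cfg$domain_fold < 1) stop("'domain_fold' must be >= 1")
  if (cfg$bg_rate < 0) stop("'bg_rate' must be >= 0")
  if (cfg$nb_dispersion < 0) stop("'nb_dispersion' must be >= 0")
  if (cfg$n_true_hdegs + cfg$n_decoys > cfg$n_genes)
    stop("n_true_hdegs + n_decoys must not exceed n_genes")
  if (is.null(stage_labels))
    stage_labels <- if (n_stages == 3) c("d33", "d65", "d90")
                    else paste0("s", seq_len(n_stages))
  stopifnot(length(stage_labels) == n_stages)
  cfg$stage_labels <- stage_labels
  structure(cfg, class = "synth_config")
}

#' Generate a miniature genome with non-overlapping gene models
#'
#' Genes are packed left to right on each chromosome with random lengths and
#' gaps; each gene gets an exon/intron structure whose transcription-first
#' and -last exons carry 5'/3' UTR sub-intervals, so all six annotation
#' feature classes are exercisable. Coordinates are 0-based half-open.
#'
#' @param cfg a [synth_config()].
#' @return a `synth_genome` list with `chrom_sizes` (named integer vector),
#'   `genes` (data.frame: gene_id, chrom, start, end, strand, tss, tes,
#'   exonic_length) and `features` (data.frame of exon and UTR intervals).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(as.integer(cfg$chrom_length),
                                     cfg$n_chroms), chroms)
  empty_genes <- data.frame(gene_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), tss = integer(),
                            tes = integer(), exonic_length = integer(),
                            stringsAsFactors = FALSE)
  empty_feat <- data.frame(gene_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           type = character(), stringsAsFactors = FALSE)
  if (cfg$n_genes == 0L)
    return(structure(list(chrom_sizes = chrom_sizes, genes = empty_genes,
                          features = empty_feat), class = "synth_genome"))
  per_chrom <- diff(floor(cfg$n_genes * (0:cfg$n_chroms) / cfg$n_chroms))
  min_gap <- 200L
  with_substream(cfg$seed, "genome", {
    genes <- list(); feats <- list(); gid <- 0L
    for (ci in seq_along(chroms)) {
      g <- per_chrom[ci]
      if (g == 0L) next
      len <- round(stats::runif(g, 1500, 4000))
      need <- sum(len) + (g + 1L) * min_gap
      if (need > cfg$chrom_length)
        stop("infeasible packing: ", g, " genes need ", need,
             " bp on a ", cfg$chrom_length, " bp chromosome")
      leftover <- cfg$chrom_length - need
      props <- diff(c(0, sort(stats::runif(g)), 1))
      extra <- floor(props * leftover)
      gaps <- min_gap + extra[seq_len(g)]
      starts <- cumsum(gaps) + c(0, cumsum(len))[seq_len(g)]
      strand <- sample(c("+", "-"), g, replace = TRUE)
      for (i in seq_len(g)) {
        gid <- gid + 1L
        id <- sprintf("g%05d", gid)
        s <- as.integer(starts[i]); e <- as.integer(starts[i] + len[i])
        ex <- .gene_exons(id, chroms[ci], s, e, strand[i])
        genes[[gid]] <- data.frame(
          gene_id = id, chrom = chroms[ci], start = s, end = e,
          strand = strand[i],
          tss = if (strand[i] == "+") s else e,
          tes = if (strand[i] == "+") e else s,
          exonic_length = sum(ex$end[ex$type == "exon"] -
                              ex$start[ex$type == "exon"]),
          stringsAsFactors = FALSE)
        feats[[gid]] <- ex
      }
    }
    genes <- do.call(rbind, genes)
    feats <- do.call(rbind, feats)
    structure(list(chrom_sizes = chrom_sizes, genes = genes,
                   features = feats), class = "synth_genome")
  })
}

# exon/intron layout for one gene plus UTR sub-intervals on the
# transcription-first and -last exons (draws from the current RNG stream)
.gene_exons <- function(id, chrom, start, end, strand) {
  L <- end - start
  n_ex <- sample(2:5, 1)
  ex_total <- round(L * stats::runif(1, 0.3, 0.6))
  ex_total <- max(ex_total, n_ex * 60L)
  in_total <- L - ex_total
  part <- function(total, k, floor_w) {
    if (k == 1L) return(total)
    as.vector(stats::rmultinom(1, total - k * floor_w,
                               prob = stats::runif(k))) + floor_w
  }
  ew <- part(ex_total, n_ex, 60L)
  iw <- part(in_total, n_ex - 1L, 50L)
  widths <- integer(2L * n_ex - 1L)
  widths[seq(1L, by = 2L, length.out = n_ex)] <- ew
  widths[seq(2L, by = 2L, length.out = n_ex - 1L)] <- iw
  bounds <- start + c(0L, cumsum(widths))
  es <- bounds[seq(1L, by = 2L, length.out = n_ex)]
  ee <- bounds[seq(2L, by = 2L, length.out = n_ex)]
  rows <- data.frame(gene_id = id, chrom = chrom, start = as.integer(es),
                     end = as.integer(ee), type = "exon",
                     stringsAsFactors = FALSE)
  u_first <- max(1L, round(0.3 * ew[1]))
  u_last <- max(1L, round(0.3 * ew[n_ex]))
  if (strand == "+") {
    utr5 <- c(es[1], es[1] + u_first)
    utr3 <- c(ee[n_ex] - u_last, ee[n_ex])
  } else {
    utr5 <- c(ee[n_ex] - u_last, ee[n_ex])
    utr3 <- c(es[1], es[1] + u_first)
  }
  rbind(rows,
        data.frame(gene_id = id, chrom = chrom,
                   start = as.integer(c(utr5[1], utr3[1])),
                   end = as.integer(c(utr5[2], utr3[2])),
                   type = c("five_prime_utr", "three_prime_utr"),
                   stringsAsFactors = FALSE))
}

#' Plan the planted ground truth for a synthetic run
#'
#' Selects planted genes with mutual TSS clearance (so no planted gene's
#' promoter overlaps another planted gene's domain), assigns each true HDEG
#' a transition, a sign, a promoter-domain presence flip opposing its
#' expression change, and baseline expression; decoys get exactly one of the
#' two changes. Non-planted genes optionally carry constant promoter domains
#' with probability anti-coupled to their baseline expression tier, plus
#' intergenic background domains, emulating the genome-wide anticorrelation
#' between the repressive mark and transcription.
#'
#' @param cfg a [synth_config()].
#' @param genome a [generate_genome()] result.
#' @return a `ground_truth` list: `planted_domains` (with a stage-presence
#'   matrix), `planted_degs`, `true_hdegs`, `decoys`, `mu` (gene-by-stage
#'   expected counts) and `baseline_mu`.
#' @export
plan_truth <- function(cfg, genome) {
  stopifnot(inherits(cfg, "synth_config"), inherits(genome, "synth_genome"))
  genes <- genome$genes
  S <- cfg$n_stages
  with_substream(cfg$seed, "truth", {
    n_pl <- cfg$n_true_hdegs + cfg$n_decoys
    # planted domains must stay beyond gap-merge distance of each other and
    # of any static domain, or a merged island's midpoint can drift outside
    # the promoter it was planted in
    min_sep <- cfg$domain_width + cfg$flank
    planted <- character(0)
    if (n_pl > 0L) {
      ord <- sample(genes$gene_id)
      tss <- stats::setNames(genes$tss, genes$gene_id)
      chr <- stats::setNames(genes$chrom, genes$gene_id)
      acc_tss <- list()
      for (g in ord) {
        prior <- acc_tss[[chr[g]]]
        if (is.null(prior) || all(abs(prior - tss[g]) >= min_sep)) {
          planted <- c(planted, g)
          acc_tss[[chr[g]]] <- c(prior, tss[g])
          if (length(planted) == n_pl) break
        }
      }
      if (length(planted) < n_pl)
        stop("could not place ", n_pl, " planted genes with ",
             min_sep, " bp TSS clearance; enlarge the genome")
    }
    hdegs <- planted[seq_len(cfg$n_true_hdegs)]
    dec <- planted[setdiff(seq_len(n_pl), seq_len(cfg$n_true_hdegs))]
    n_ed <- ceiling(length(dec) / 2)
    decoys <- data.frame(
      gene_id = dec,
      mode = rep(c("expression_only", "domain_only"),
                 c(n_ed, length(dec) - n_ed)),
      stringsAsFactors = FALSE)

    # baseline expression: planted genes are solidly expressed; the rest is
    # a silent/lognormal mixture wide enough to spread the quartile classes
    mu0 <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
    nonpl <- setdiff(genes$gene_id, planted)
    silent <- stats::runif(length(nonpl)) < cfg$p_silent
    mu0[nonpl] <- ifelse(silent, 0, stats::rlnorm(length(nonpl),
                                                  log(30), 1.2))
    mu0[planted] <- stats::rlnorm(length(planted), log(100), 0.4)

    # per-gene stage means and domain presence for planted genes
    mu <- matrix(rep(mu0, S), ncol = S,
                 dimnames = list(genes$gene_id, cfg$stage_labels))
    deg_rows <- list(); dom_rows <- list(); pres <- list(); di <- 0L
    plant_one <- function(g, expr_change, dom_change) {
      tr <- if (S > 2) sample(seq_len(S - 1L), 1) else 1L
      sgn <- sample(c(1L, -1L), 1)
      if (expr_change) {
        shift <- 2^(sgn * cfg$lfc_planted)
        after <- seq(tr + 1L, S)
        if (sgn > 0) mu[g, after] <<- mu0[g] * shift
        else { mu[g, seq_len(tr)] <<- mu0[g] * 2^cfg$lfc_planted }
        deg_rows[[length(deg_rows) + 1L]] <<- data.frame(
          gene_id = g, transition = tr, sign = sgn,
          log2fc = sgn * cfg$lfc_planted, stringsAsFactors = FALSE)
      }
      if (dom_change) {
        di <<- di + 1L
        gi <- match(g, genes$gene_id)
        st <- max(0L, as.integer(genes$tss[gi] - cfg$domain_width / 2))
        en <- min(genome$chrom_sizes[[genes$chrom[gi]]],
                  as.integer(genes$tss[gi] + cfg$domain_width / 2))
        # mark present where expression is low: up-genes lose the domain at
        # the transition, down-genes gain it
        p <- if (sgn > 0) c(rep(1L, tr), rep(0L, S - tr))
             else c(rep(0L, tr), rep(1L, S - tr))
        dom_rows[[di]] <<- data.frame(
          domain_id = sprintf("dom%05d", di), gene_id = g,
          chrom = genes$chrom[gi], start = st, end = en,
          kind = if (expr_change) "hdeg" else "decoy_domain",
          stringsAsFactors = FALSE)
        pres[[di]] <<- p
      }
    }
    for (g in hdegs) plant_one(g, TRUE, TRUE)
    if (nrow(decoys))
      for (i in seq_len(nrow(decoys)))
        plant_one(decoys$gene_id[i],
                  decoys$mode[i] == "expression_only",
                  decoys$mode[i] == "domain_only")

    # constant promoter domains on non-planted genes, anti-coupled to tier;
    # tiers follow the expected TPM so they align with the realized
    # expression classes (silent = expected TPM below the expressed rule)
    if (any(cfg$coupling > 0) && length(nonpl)) {
      rate_all <- mu0 / genes$exonic_length[match(names(mu0), genes$gene_id)]
      etpm <- rate_all / sum(rate_all) * 1e6
      tier <- rep("silent", length(nonpl))
      on <- etpm[nonpl] >= 0.5
      if (sum(on) >= 4) {
        q <- stats::quantile(etpm[nonpl][on], c(0.25, 0.75), type = 7)
        tier[on] <- ifelse(etpm[nonpl][on] >= q[2], "high",
                      ifelse(etpm[nonpl][on] <= q[1], "low", "medium"))
      } else tier[on] <- "medium"
      keep_dom <- stats::runif(length(nonpl)) < cfg$coupling[tier]
      pl_tss <- genes[match(planted, genes$gene_id), c("chrom", "tss")]
      for (j in which(keep_dom)) {
        g <- nonpl[j]; gi <- match(g, genes$gene_id)
        st <- max(0L, as.integer(genes$tss[gi] - cfg$domain_width / 2))
        en <- min(genome$chrom_sizes[[genes$chrom[gi]]],
                  as.integer(genes$tss[gi] + cfg$domain_width / 2))
        clear <- cfg$domain_width / 2 + cfg$flank
        near <- pl_tss$chrom == genes$chrom[gi] &
          pl_tss$tss > st - clear & pl_tss$tss < en + clear
        if (any(near)) next  # keep planted domains isolated from static marks
        di <- di + 1L
        dom_rows[[di]] <- data.frame(
          domain_id = sprintf("dom%05d", di), gene_id = g,
          chrom = genes$chrom[gi], start = st, end = en, kind = "coupled",
          stringsAsFactors = FALSE)
        pres[[di]] <- rep(1L, S)
      }
    }

    # intergenic background domains, constant across stages
    if (cfg$n_bg_domains > 0L && nrow(genes)) {
      for (k in seq_len(cfg$n_bg_domains)) {
        for (att in seq_len(50L)) {
          cidx <- sample(length(genome$chrom_sizes), 1)
          cs <- genome$chrom_sizes[cidx]
          st <- floor(stats::runif(1, 0, cs - cfg$bg_domain_width))
          en <- st + cfg$bg_domain_width
          gg <- genes[genes$chrom == names(cs), ]
          lo <- pmin(gg$start, gg$tss - cfg$flank)
          hi <- pmax(gg$end, gg$tss + cfg$flank)
          if (!any(st < hi & en > lo)) {
            di <- di + 1L
            dom_rows[[di]] <- data.frame(
              domain_id = sprintf("dom%05d", di), gene_id = NA_character_,
              chrom = names(cs), start = as.integer(st), end = as.integer(en),
              kind = "intergenic", stringsAsFactors = FALSE)
            pres[[di]] <- rep(1L, S)
            break
          }
        }
      }
    }

    domains <- if (di > 0L) do.call(rbind, dom_rows) else
      data.frame(domain_id = character(), gene_id = character(),
                 chrom = character(), start = integer(), end = integer(),
                 kind = character(), stringsAsFactors = FALSE)
    presence <- if (di > 0L) do.call(rbind, pres) else
      matrix(integer(0), 0, S)
    colnames(presence) <- cfg$stage_labels
    truth <- structure(list(
      planted_domains = domains, presence = presence,
      planted_degs = if (length(deg_rows)) do.call(rbind, deg_rows) else
        data.frame(gene_id = character(), transition = integer(),
                   sign = integer(), log2fc = numeric(),
                   stringsAsFactors = FALSE),
      true_hdegs = hdegs, decoys = decoys,
      baseline_mu = mu0, mu = mu), class = "ground_truth")
    .check_truth(truth, cfg)
    truth
  })
}

# every true HDEG must have, for its transition, a promoter domain whose
# presence flips opposite to the planted expression sign
.check_truth <- function(truth, cfg) {
  for (g in truth$true_hdegs) {
    d <- truth$planted_degs[truth$planted_degs$gene_id == g, ]
    idx <- which(truth$planted_domains$gene_id == g &
                 truth$planted_domains$kind == "hdeg")
    stopifnot(length(idx) == 1L)
    p <- truth$presence[idx, ]
    flip <- p[d$transition + 1L] - p[d$transition]
    stopifnot(sign(flip) == -d$sign)
  }
  invisible(TRUE)
}

#' Generate ChIP fragment sets with planted broad domains
#'
#' The input channel is homogeneous Poisson at `bg_rate` fragments per bp;
#' the IP channel multiplies the rate by `domain_fold` inside planted domains
#' present at that stage. Fragments are fixed-length intervals; MAPQ values
#' and exact duplicates are injected at configurable fractions to exercise
#' the filtering step.
#'
#' @param cfg a [synth_config()].
#' @param genome a [generate_genome()] result.
#' @param truth optional [plan_truth()] result; planned internally if NULL.
#' @return list with `fragments` (nested: stage -> channel ("ip"/"input") ->
#'   list of `fragment_set`s) and `truth`.
#' @export
generate_chip <- function(cfg, genome, truth = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(genome, "synth_genome"))
  if (is.null(truth)) truth <- plan_truth(cfg, genome)
  dom <- truth$planted_domains
  if (nrow(dom)) {
    cs <- genome$chrom_sizes[dom$chrom]
    if (any(dom$start < 0 | dom$end > cs))
      stop("planted domain outside chromosome")
  }
  frag_sets <- list()
  for (s in seq_len(cfg$n_stages)) {
    st_lab <- cfg$stage_labels[s]
    frag_sets[[st_lab]] <- list(ip = list(), input = list())
    for (ch in c("ip", "input")) {
      for (r in seq_len(cfg$reps_chip)) {
        lab <- sprintf("chip:%s:%s:rep%d", st_lab, ch, r)
        fs <- with_substream(cfg$seed, lab, {
          .simulate_sample(cfg, genome, dom, truth$presence[, s],
                           enriched = (ch == "ip"))
        })
        frag_sets[[st_lab]][[ch]][[r]] <-
          fragment_set(fs, stage = st_lab, rep = r, channel = ch)
      }
    }
  }
  list(fragments = frag_sets, truth = truth)
}

# one sample's fragments: Poisson background everywhere plus, for the IP
# channel, extra fragments whose midpoints fall inside active domains
.simulate_sample <- function(cfg, genome, dom, presence, enriched) {
  out <- list()
  for (cn in names(genome$chrom_sizes)) {
    size <- genome$chrom_sizes[[cn]]
    n_bg <- stats::rpois(1, size * cfg$bg_rate)
    starts <- floor(stats::runif(n_bg, 0, max(1, size - cfg$frag_len)))
    if (enriched && nrow(dom) && cfg$domain_fold > 1) {
      act <- dom[dom$chrom == cn & presence == 1L, , drop = FALSE]
      if (nrow(act)) {
        for (i in seq_len(nrow(act))) {
          wdt <- act$end[i] - act$start[i]
          n_e <- stats::rpois(1, wdt * cfg$bg_rate * (cfg$domain_fold - 1))
          if (n_e > 0) {
            s_e <- floor(stats::runif(n_e, act$start[i] - cfg$frag_len / 2,
                                      act$end[i] - cfg$frag_len / 2))
            s_e <- pmin(pmax(s_e, 0), size - cfg$frag_len)
            starts <- c(starts, s_e)
          }
        }
      }
    }
    if (length(starts))
      out[[cn]] <- data.frame(chrom = cn, start = as.integer(starts),
                              end = as.integer(starts + cfg$frag_len),
                              stringsAsFactors = FALSE)
  }
  frags <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  n <- nrow(frags)
  if (n) {
    low <- stats::runif(n) < cfg$frac_lowmapq
    frags$mapq <- ifelse(low, sample(0:19, n, replace = TRUE),
                         sample(20:60, n, replace = TRUE))
    n_dup <- floor(n * cfg$dup_frac)
    if (n_dup > 0) frags <- rbind(frags, frags[sample(n, n_dup), ])
  } else frags$mapq <- integer(0)
  rownames(frags) <- NULL
  frags
}

#' Construct a fragment set
#'
#' @param frags data.frame with columns chrom, start, end and optionally
#'   mapq; 0-based half-open coordinates.
#' @param stage,rep,channel sample labels.
#' @return a `fragment_set` whose `library_size` is the current fragment
#'   count (updated by [filter_fragments()]).
#' @export
fragment_set <- function(frags, stage = NA, rep = NA, channel = NA) {
  stopifnot(all(c("chrom", "start", "end") %in% names(frags)))
  structure(list(frags = frags, stage = stage, rep = rep, channel = channel,
                 library_size = nrow(frags)), class = "fragment_set")
}

#' Generate a negative-binomial count matrix from planted truth
#'
#' Counts follow NB(mu_gs, dispersion alpha) with the stage means recorded
#' in the ground truth; `nb_dispersion = 0` gives Poisson counts.
#'
#' @param cfg a [synth_config()].
#' @param genome a [generate_genome()] result.
#' @param truth a [plan_truth()] result (also returned by [generate_chip()]).
#' @return a [count_matrix()] with genes x (stages x reps_rna) counts.
#' @export
generate_counts <- function(cfg, genome, truth) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "ground_truth"))
  G <- nrow(genome$genes)
  cols <- list(); stages <- character(0)
  for (s in seq_len(cfg$n_stages)) {
    for (r in seq_len(cfg$reps_rna)) {
      lab <- sprintf("rna:%s:rep%d", cfg$stage_labels[s], r)
      mu_s <- truth$mu[, s]
      cnt <- with_substream(cfg$seed, lab, {
        if (cfg$nb_dispersion == 0) stats::rpois(G, mu_s)
        else stats::rnbinom(G, mu = mu_s, size = 1 / cfg$nb_dispersion)
      })
      cols[[sprintf("%s_r%d", cfg$stage_labels[s], r)]] <- cnt
      stages <- c(stages, cfg$stage_labels[s])
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- genome$genes$gene_id
  count_matrix(m, stages = stages,
               gene_lengths = stats::setNames(genome$genes$exonic_length,
                                              genome$genes$gene_id))
}

#' Run the full synthetic generator
#'
#' Convenience wrapper: genome, ground truth, ChIP fragments and counts.
#'
#' @param cfg a [synth_config()].
#' @return list(genome, truth, fragments, counts).
#' @export
generate_synthetic <- function(cfg) {
  genome <- generate_genome(cfg)
  chip <- generate_chip(cfg, genome)
  counts <- generate_counts(cfg, genome, chip$truth)
  list(genome = genome, truth = chip$truth, fragments = chip$fragments,
       counts = counts)
}
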