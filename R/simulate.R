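#' @name synthetic_data
#' @title Seeded synthetic organelle data with ground-truth manifests
#'
#' @description
#' Generates a desk-scale study system: a circular mitochondrial genome
#' with planted protein-coding genes, microsatellites, tandem arrays,
#' dispersed repeats (all four orientation classes), plastid-derived
#' insertions copied verbatim from a companion circular plastid genome,
#' and C-to-U editing sites; a linear random nuclear sequence; and
#' mixed-origin long reads with configurable error. Every planted
#' feature is recorded in a manifest with exact coordinates, so each
#' detector in the package can be validated for recall against ground
#' truth. All randomness flows through the single seed in the
#' configuration: the same seed gives byte-identical output.
NULL

.DEFAULT_GENES <- data.frame(
  name = c("atp1", "atp4", "atp6", "atp8", "atp9", "cob", "cox1", "cox2",
           "cox3", "nad1", "nad3", "nad4", "nad6", "rps4", "matR"),
  length = c(1527L, 579L, 720L, 480L, 225L, 1170L, 1584L, 783L, 798L,
             978L, 357L, 1479L, 618L, 819L, 1968L),
  strand = c("+", "-", "+", "+", "-", "+", "+", "-", "+", "-", "+", "+",
             "-", "+", "+"),
  stringsAsFactors = FALSE)

.DEFAULT_SSRS <- data.frame(
  motif = c("A", "T", "AG", "AT", "CT", "AAG", "ACT", "AATC", "AACTG",
            "AACGTC"),
  copies = c(12L, 11L, 6L, 7L, 6L, 5L, 5L, 4L, 3L, 3L),
  stringsAsFactors = FALSE)

.DEFAULT_TANDEMS <- data.frame(unit_length = c(20L, 35L),
                               copies = c(4L, 3L),
                               mismatches = c(0L, 1L))

.DEFAULT_DISPERSED <- data.frame(
  length = c(60L, 45L, 80L, 50L),
  class = c("forward", "palindromic", "palindromic", "forward"),
  stringsAsFactors = FALSE)

#' Configuration for the synthetic study system
#'
#' Defaults define the study conditions used throughout the package's
#' validation: a 60 kb circular mitogenome at 44.9% GC with 15 planted
#' core genes, repeats of all three classes well above the detection
#' thresholds, three short plastid insertions (total about 2.4% of the
#' mitogenome), a 20 kb plastid, a 200 kb nuclear sequence, and a read
#' pool of 2,000 reads mixed 5% mito / 15% plastid / 80% nuclear with
#' 10% uniform error (substitutions:indels 3:1) and gamma-distributed
#' lengths around 5 kb.
#'
#' @param genome_length,plastid_length,nuclear_length sizes in bp.
#' @param gc_target backbone GC fraction.
#' @param gene_specs data.frame `name`, `length` (CDS bp excluding the
#'   stop codon), `strand`.
#' @param ssr_specs data.frame `motif`, `copies`.
#' @param tandem_specs data.frame `unit_length`, `copies`, `mismatches`.
#' @param dispersed_specs data.frame `length`, `class`.
#' @param insertion_specs integer vector of plastid insertion lengths,
#'   or a data.frame `length`, `cp_start` (NA for random source).
#' @param edit_specs data.frame `gene`, `n_sites`; default 3 sites in
#'   each of the first ten genes.
#' @param read_mixture named fractions (mito, plastid, nuclear), sum 1.
#' @param n_reads number of reads.
#' @param read_length_mean,read_length_shape gamma length model.
#' @param error_rate total per-base error (subs:ins:del = 6:1:1).
#' @param seed integer seed; mandatory determinism.
#' @return a list of class `synthetic_config`.
#' @export
syntheticConfig <- function(genome_length = 60000L, gc_target = 0.449,
                            plastid_length = 20000L,
                            nuclear_length = 200000L,
                            gene_specs = .DEFAULT_GENES,
                            ssr_specs = .DEFAULT_SSRS,
                            tandem_specs = .DEFAULT_TANDEMS,
                            dispersed_specs = .DEFAULT_DISPERSED,
                            insertion_specs = c(150L, 500L, 800L),
                            edit_specs = NULL,
                            read_mixture = c(mito = 0.05, plastid = 0.15,
                                             nuclear = 0.80),
                            n_reads = 2000L, read_length_mean = 5000,
                            read_length_shape = 5, error_rate = 0.10,
                            seed = 1L) {
  if (abs(sum(read_mixture) - 1) > 1e-8)
    stop("read_mixture fractions must sum to 1")
  if (is.null(edit_specs))
    edit_specs <- data.frame(gene = head(gene_specs$name, 10L),
                             n_sites = 3L)
  if (is.numeric(insertion_specs) && is.null(dim(insertion_specs)))
    insertion_specs <- data.frame(
      length = as.integer(insertion_specs),
      cp_start = rep(NA_integer_, length(insertion_specs)))
  structure(list(genome_length = as.integer(genome_length),
                 gc_target = gc_target,
                 plastid_length = as.integer(plastid_length),
                 nuclear_length = as.integer(nuclear_length),
                 gene_specs = gene_specs, ssr_specs = ssr_specs,
                 tandem_specs = tandem_specs,
                 dispersed_specs = dispersed_specs,
                 insertion_specs = insertion_specs,
                 edit_specs = edit_specs, read_mixture = read_mixture,
                 n_reads = as.integer(n_reads),
                 read_length_mean = read_length_mean,
                 read_length_shape = read_length_shape,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

# break any perfect microsatellite run at or above the MISA thresholds by
# point mutations; used to keep the random backbone free of unplanted
# SSRs so that planted-feature tallies are exact
.scrubRuns <- function(s, thresholds = c("1" = 10, "2" = 5, "3" = 4,
                                         "4" = 3, "5" = 3, "6" = 3)) {
  ch <- .chars(s)
  n <- length(ch)
  for (pass in 1:5) {
    dirty <- FALSE
    for (u in 1:6) {
      thr <- as.integer(thresholds[[as.character(u)]])
      if (n <= u) next
      m <- ch[seq_len(n - u)] == ch[(u + 1L):n]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values & (r$lengths + u) %/% u >= thr)) {
        i <- starts[j] + (r$lengths[j] %/% 2L)
        avoid <- unique(c(ch[i], if (i > u) ch[i - u],
                          if (i + u <= n) ch[i + u]))
        choices <- setdiff(.BASES, avoid)
        if (!length(choices)) choices <- setdiff(.BASES, ch[i])
        ch[i] <- choices[1]
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  paste(ch, collapse = "")
}

# random in-frame CDS: given the length including the start codon but
# excluding the stop codon; no internal stops, no SSR-grade runs; codon
# usage weighted to approximate the target GC so planted genes do not
# distort whole-genome base composition
.randomCds <- function(len, gc = 0.449, start_codon = "ATG",
                       stop_codon = "TAA") {
  stopifnot(len %% 3L == 0L)
  tab <- .codonTable()
  sense <- names(tab)[tab != "X"]
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  wt <- vapply(sense, function(co) prod(pb[.chars(co)]), numeric(1))
  for (try in 1:50) {
    body <- paste(sample(sense, len / 3L - 1L, replace = TRUE, prob = wt),
                  collapse = "")
    cds <- paste0(start_codon, body, stop_codon)
    if (identical(cds, .scrubRuns(cds))) return(cds)
  }
  stop("could not generate a run-free CDS of length ", len)
}

.placeFeature <- function(L, len, occupied, margin = 10L, tries = 500L) {
  for (i in seq_len(tries)) {
    start <- sample.int(L - len - margin, 1L) + margin
    iv <- IRanges::IRanges(start - margin, start + len - 1L + margin)
    if (length(occupied) == 0L ||
        sum(IRanges::countOverlaps(iv, occupied)) == 0L)
      return(list(start = start,
                  occupied = c(occupied,
                               IRanges::IRanges(start, start + len - 1L))))
  }
  stop("config error: cannot place a feature of length ", len,
       " without overlap")
}

#' Generate the synthetic genomes and their truth manifest
#'
#' @param config a [syntheticConfig()].
#' @return list with `mito`, `plastid`, `nuclear`
#'   ([GenomeRecord-class]; mito and plastid circular), `genes` (list of
#'   [GeneModel-class] on the mitogenome) and `manifest`, a list of
#'   data.frames/vectors recording every planted feature: `genes`
#'   (coordinates), `cds` (named CDS strings), `core_genes` (same, used
#'   as recruitment baits), `ssrs`, `tandems`, `dispersed`,
#'   `insertions`, `edits`, `plastid_genes`.
#' @export
makeGenomes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  L <- config$genome_length
  mito <- .chars(.scrubRuns(.randomDNA(L, config$gc_target)))
  plastid_s <- .scrubRuns(.randomDNA(config$plastid_length, 0.38))
  nuclear_s <- .randomDNA(config$nuclear_length, 0.36)
  occupied <- IRanges::IRanges()

  # protein-coding genes
  gs <- config$gene_specs
  cds_list <- character(0)
  gene_rows <- list()
  gene_models <- list()
  for (i in seq_len(nrow(gs))) {
    cds <- .randomCds(gs$length[i], gc = config$gc_target)
    placed_len <- nchar(cds)
    pl <- .placeFeature(L, placed_len, occupied)
    occupied <- pl$occupied
    insert <- if (gs$strand[i] == "-") revComp(cds) else cds
    mito[pl$start:(pl$start + placed_len - 1L)] <- .chars(insert)
    cds_list[gs$name[i]] <- cds
    gene_rows[[i]] <- data.frame(name = gs$name[i], start = pl$start,
                                 end = pl$start + placed_len - 1L,
                                 strand = gs$strand[i],
                                 cds_length = placed_len)
    gene_models[[i]] <- GeneModel(
      gs$name[i], IRanges::IRanges(pl$start, pl$start + placed_len - 1L),
      strand = gs$strand[i], category = "protein-coding")
  }

  # microsatellites
  ssr_rows <- list()
  for (i in seq_len(nrow(config$ssr_specs))) {
    motif <- toupper(config$ssr_specs$motif[i])
    copies <- config$ssr_specs$copies[i]
    seqr <- strrep(motif, copies)
    len <- nchar(seqr)
    u <- nchar(motif)
    pl <- .placeFeature(L, len, occupied)
    occupied <- pl$occupied
    st <- pl$start
    mito[st:(st + len - 1L)] <- .chars(seqr)
    # break periodicity at both flanks so the planted run is maximal
    lf <- st - 1L
    if (lf >= 1L) {
      bad <- c(mito[lf + u], mito[lf])
      mito[lf] <- setdiff(.BASES, bad)[1]
    }
    rf <- st + len
    if (rf <= L) {
      bad <- c(mito[rf - u], mito[rf])
      mito[rf] <- setdiff(.BASES, bad)[1]
    }
    ssr_rows[[i]] <- data.frame(motif = .minRotation(motif),
                                unit_length = u, copies = copies,
                                start = st, end = st + len - 1L)
  }

  # tandem arrays
  tandem_rows <- list()
  for (i in seq_len(nrow(config$tandem_specs))) {
    p <- config$tandem_specs$unit_length[i]
    copies <- config$tandem_specs$copies[i]
    nmis <- config$tandem_specs$mismatches[i]
    repeat {
      unit <- .randomDNA(p, 0.5)
      arr <- strrep(unit, copies)
      if (!.isNonPrimitive(unit) && identical(arr, .scrubRuns(arr))) break
    }
    ach <- .chars(arr)
    if (nmis > 0L) {
      # substitutions outside the first copy keep the consensus = unit
      mpos <- sample((p + 1L):length(ach), nmis)
      for (mp in mpos) ach[mp] <- setdiff(.BASES, ach[mp])[1]
    }
    len <- length(ach)
    pl <- .placeFeature(L, len, occupied)
    occupied <- pl$occupied
    st <- pl$start
    mito[st:(st + len - 1L)] <- ach
    lf <- st - 1L
    if (lf >= 1L) mito[lf] <- setdiff(.BASES, c(mito[lf + p], mito[lf]))[1]
    rf <- st + len
    if (rf <= L) mito[rf] <- setdiff(.BASES, c(mito[rf - p], mito[rf]))[1]
    tandem_rows[[i]] <- data.frame(period = p, copies = copies,
                                   mismatches = nmis, start = st,
                                   end = st + len - 1L, unit = unit)
  }

  # dispersed repeat pairs
  disp_rows <- list()
  for (i in seq_len(nrow(config$dispersed_specs))) {
    len <- config$dispersed_specs$length[i]
    cls <- config$dispersed_specs$class[i]
    repeat {
      a <- .randomDNA(len, 0.5)
      if (identical(a, .scrubRuns(a)) && !.isNonPrimitive(a)) break
    }
    b <- switch(cls, forward = a, palindromic = revComp(a),
                reverse = .rev(a), complement = .comp(a),
                stop("unknown dispersed class: ", cls))
    pl1 <- .placeFeature(L, len, occupied); occupied <- pl1$occupied
    pl2 <- .placeFeature(L, len, occupied); occupied <- pl2$occupied
    mito[pl1$start:(pl1$start + len - 1L)] <- .chars(a)
    mito[pl2$start:(pl2$start + len - 1L)] <- .chars(b)
    iv <- data.frame(a_start = pl1$start, a_end = pl1$start + len - 1L,
                     b_start = pl2$start, b_end = pl2$start + len - 1L)
    if (iv$b_start < iv$a_start)
      iv <- data.frame(a_start = iv$b_start, a_end = iv$b_end,
                       b_start = iv$a_start, b_end = iv$a_end)
    disp_rows[[i]] <- cbind(data.frame(class = cls, length = len), iv)
  }

  # plastid-derived insertions, copied verbatim (the MTPT ground truth)
  ins_rows <- list()
  isp <- config$insertion_specs
  for (i in seq_len(nrow(isp))) {
    len <- isp$length[i]
    cp_start <- isp$cp_start[i]
    if (is.na(cp_start))
      cp_start <- sample.int(config$plastid_length - len, 1L)
    frag <- substr(plastid_s, cp_start, cp_start + len - 1L)
    pl <- .placeFeature(L, len, occupied)
    occupied <- pl$occupied
    mito[pl$start:(pl$start + len - 1L)] <- .chars(frag)
    ins_rows[[i]] <- data.frame(mt_start = pl$start,
                                mt_end = pl$start + len - 1L,
                                cp_start = cp_start,
                                cp_end = cp_start + len - 1L,
                                length = len)
  }

  # editing sites: C at codon position 1 or 2, inside planted gene CDS
  edit_rows <- list()
  for (i in seq_len(nrow(config$edit_specs))) {
    gn <- config$edit_specs$gene[i]
    nsites <- config$edit_specs$n_sites[i]
    cds <- cds_list[[gn]]
    ch <- .chars(cds)
    ncod <- nchar(cds) / 3L
    cand <- which(ch == "C")
    cand <- cand[((cand - 1L) %% 3L + 1L) %in% c(1L, 2L)]
    cand <- cand[cand <= (ncod - 1L) * 3L]  # not in the stop codon
    if (length(cand) < nsites)
      stop("config error: gene ", gn, " has too few editable C sites")
    sites <- sort(sample(cand, nsites))
    edit_rows[[i]] <- data.frame(gene = gn, cds_position = sites)
  }

  mito_s <- paste(mito, collapse = "")
  manifest <- list(
    genes = do.call(rbind, gene_rows),
    cds = cds_list,
    core_genes = cds_list,
    ssrs = if (length(ssr_rows)) do.call(rbind, ssr_rows) else NULL,
    tandems = if (length(tandem_rows)) do.call(rbind, tandem_rows)
              else NULL,
    dispersed = if (length(disp_rows)) do.call(rbind, disp_rows)
                else NULL,
    insertions = if (length(ins_rows)) do.call(rbind, ins_rows) else NULL,
    edits = if (length(edit_rows)) do.call(rbind, edit_rows) else NULL,
    plastid_genes = NULL)
  list(mito = GenomeRecord("mito_synth", mito_s, circular = TRUE),
       plastid = GenomeRecord("plastid_synth", plastid_s,
                              circular = TRUE),
       nuclear = GenomeRecord("nuclear_synth", nuclear_s,
                              circular = FALSE),
       genes = gene_models, manifest = manifest)
}

# apply uniform sequencing errors; subs:ins:del = 6:1:1 of error_rate
.mutateRead <- function(ch, error_rate) {
  if (error_rate <= 0) return(ch)
  n <- length(ch)
  sub_p <- 0.75 * error_rate
  ind_p <- 0.125 * error_rate
  u <- runif(n)
  subs <- u < sub_p
  del <- u >= sub_p & u < sub_p + ind_p
  ins <- u >= sub_p + ind_p & u < sub_p + 2 * ind_p
  if (any(subs)) {
    shift <- sample.int(3L, sum(subs), replace = TRUE)
    ch[subs] <- .BASES[(match(ch[subs], .BASES) - 1L + shift) %% 4L + 1L]
  }
  counts <- ifelse(del, 0L, ifelse(ins, 2L, 1L))
  idx <- rep(seq_len(n), counts)
  out <- ch[idx]
  dup <- duplicated(idx) & c(FALSE, idx[-1] == idx[-length(idx)])
  if (any(dup)) out[dup] <- sample(.BASES, sum(dup), replace = TRUE)
  out
}

#' Simulate mixed-origin long reads with truth labels
#'
#' Read origins follow the configured mixture, lengths are
#' gamma-distributed about the mean (clamped to [200, 0.9 x genome]),
#' circular genomes are sampled across the origin, strands are random,
#' and uniform substitution/indel errors are applied at the configured
#' rate. Reproducible from `config$seed`.
#'
#' @param genomes result of [makeGenomes()].
#' @param config the same [syntheticConfig()].
#' @return list with `reads` (named character vector), `labels` (named,
#'   one of mito/plastid/nuclear), `info` (data.frame read, label,
#'   length, start, strand).
#' @export
makeReads <- function(genomes, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  mix <- config$read_mixture
  n <- config$n_reads
  origin <- sample(names(mix), n, replace = TRUE, prob = mix)
  srcs <- list(mito = genomes$mito, plastid = genomes$plastid,
               nuclear = genomes$nuclear)
  lens <- pmax(200L, round(rgamma(n, shape = config$read_length_shape,
                                  rate = config$read_length_shape /
                                         config$read_length_mean)))
  reads <- character(n)
  info <- vector("list", n)
  for (i in seq_len(n)) {
    g <- srcs[[origin[i]]]
    Lg <- genomeLength(g)
    len <- min(lens[i], as.integer(0.9 * Lg))
    s <- genomeSeq(g)
    if (isCircular(g)) {
      start <- sample.int(Lg, 1L)
      s2 <- if (start + len - 1L > Lg) paste0(s, s) else s
      frag <- substr(s2, start, start + len - 1L)
    } else {
      start <- sample.int(Lg - len + 1L, 1L)
      frag <- substr(s, start, start + len - 1L)
    }
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") frag <- revComp(frag)
    frag <- paste(.mutateRead(.chars(frag), config$error_rate),
                  collapse = "")
    reads[i] <- frag
    info[[i]] <- data.frame(read = sprintf("read%05d", i),
                            label = origin[i], length = nchar(frag),
                            start = start, strand = strand)
  }
  info <- do.call(rbind, info)
  names(reads) <- info$read
  labels <- setNames(info$label, info$read)
  list(reads = reads, labels = labels, info = info)
}

#' Simulate a divergent CDS pair with synonymous/nonsynonymous budgets
#'
#' Single-base changes are proposed at random codon positions and
#' accepted while the corresponding budget (synonymous:
#' `ks_target x S`; nonsynonymous: `omega_target x ks_target x N`, with
#' S and N the NG86 site counts of the input) is unfilled; changes
#' creating stop codons are rejected. Realized counts are recorded for
#' oracle checks.
#'
#' At most one position per codon is mutated, so that every realized
#' change has an unambiguous synonymous/nonsynonymous identity (no
#' pathway ambiguity in multi-hit codons).
#'
#' @param cds in-frame CDS without internal stops (terminal stop
#'   allowed; it is never mutated).
#' @param omega_target target Ka/Ks ratio (0 for synonymous-only).
#' @param ks_target target synonymous substitutions per synonymous site.
#' @param seed integer seed.
#' @param max_tries proposal budget multiplier (default 200).
#' @return list with `a` (input), `b` (mutated), `syn`, `nonsyn`
#'   (realized counts), `sites_s`, `sites_n`.
#' @export
makeDivergentPair <- function(cds, omega_target, ks_target, seed,
                              max_tries = 200L) {
  set.seed(seed)
  cds <- toupper(cds)
  co <- .codons(cds)
  k <- length(co)
  mutable <- which(translateCodon(co) != "X")
  sites <- vapply(co[mutable], .ng86SiteCodon, numeric(2))
  S <- sum(sites["syn", ]); N <- sum(sites["nonsyn", ])
  syn_budget <- round(ks_target * S)
  non_budget <- round(omega_target * ks_target * N)
  ch <- .chars(cds)
  used <- logical(k)  # one mutation per codon at most
  syn <- 0L; non <- 0L
  tries <- 0L
  max_attempts <- max_tries * max(1L, syn_budget + non_budget)
  while ((syn < syn_budget || non < non_budget) && tries < max_attempts) {
    tries <- tries + 1L
    ci <- mutable[sample.int(length(mutable), 1L)]
    p <- sample.int(3L, 1L)
    pos <- (ci - 1L) * 3L + p
    if (used[ci]) next
    cur <- paste(ch[(ci - 1L) * 3L + 1:3], collapse = "")
    alt <- sample(setdiff(.BASES, ch[pos]), 1L)
    mut <- .chars(cur); mut[p] <- alt
    mutc <- paste(mut, collapse = "")
    aa0 <- translateCodon(cur); aa1 <- translateCodon(mutc)
    if (aa1 == "X") next
    is_syn <- aa1 == aa0
    if (is_syn && syn >= syn_budget) next
    if (!is_syn && non >= non_budget) next
    ch[pos] <- alt
    used[ci] <- TRUE
    if (is_syn) syn <- syn + 1L else non <- non + 1L
  }
  if (syn < syn_budget || non < non_budget)
    stop("mutation budgets unattainable on this CDS (wanted ",
         syn_budget, " syn / ", non_budget, " nonsyn, realized ",
         syn, "/", non, ")")
  list(a = cds, b = paste(ch, collapse = ""), syn = syn, nonsyn = non,
       sites_s = S, sites_n = N)
}

#' Check a truth manifest against the emitted genomes
#'
#' Re-reads every recorded feature interval from the generated sequences
#' and verifies it matches the recorded content (genes: the planted CDS;
#' insertions: the plastid source fragment; repeats: periodicity or copy
#' equality). Returns TRUE invisibly or stops with the first mismatch.
#'
#' @param genomes result of [makeGenomes()].
#' @return TRUE, invisibly.
#' @export
validateManifest <- function(genomes) {
  man <- genomes$manifest
  s <- genomeSeq(genomes$mito)
  for (i in seq_len(nrow(man$genes))) {
    g <- man$genes[i, ]
    seg <- substr(s, g$start, g$end)
    if (g$strand == "-") seg <- revComp(seg)
    if (!identical(seg, unname(man$cds[[g$name]])))
      stop("manifest mismatch for gene ", g$name)
  }
  if (!is.null(man$insertions)) {
    ps <- genomeSeq(genomes$plastid)
    for (i in seq_len(nrow(man$insertions))) {
      r <- man$insertions[i, ]
      if (!identical(substr(s, r$mt_start, r$mt_end),
                     substr(ps, r$cp_start, r$cp_end)))
        stop("manifest mismatch for insertion ", i)
    }
  }
  if (!is.null(man$dispersed)) {
    for (i in seq_len(nrow(man$dispersed))) {
      r <- man$dispersed[i, ]
      a <- substr(s, r$a_start, r$a_end)
      b <- substr(s, r$b_start, r$b_end)
      expect <- switch(r$class, forward = a, palindromic = revComp(a),
                       reverse = .rev(a), complement = .comp(a))
      if (!identical(b, expect) && !identical(a, switch(r$class,
            forward = b, palindromic = revComp(b), reverse = .rev(b),
            complement = .comp(b))))
        stop("manifest mismatch for dispersed repeat ", i)
    }
  }
  invisible(TRUE)
}
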