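# Synthetic communities with known ground truth: peptide/genome generation,
# log-normal per-genome sequencing depths, homologous reference families
# (conserved cores and shared domains inducing genuine multi-mapping), and
# paired-end read simulation.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

# sense codons grouped by amino acid (standard genetic code)
codons_by_aa <- function() {
  if (is.null(.cdsem$codons)) {
    gc <- Biostrings::GENETIC_CODE
    gc <- gc[gc != "*"]
    .cdsem$codons <- split(names(gc), gc)
  }
  .cdsem$codons
}

# bulk random peptide strings drawn from the current RNG stream
rand_aa_strings <- function(lengths) {
  if (length(lengths) == 0) return(character(0))
  chars <- sample(AA20, sum(lengths), replace = TRUE)
  grp <- rep(seq_along(lengths), lengths)
  out <- vapply(split(chars, grp), paste, character(1), collapse = "")
  unname(out[as.character(seq_along(lengths))])
}

rand_dna_strings <- function(lengths) {
  if (length(lengths) == 0) return(character(0))
  chars <- sample(c("A", "C", "G", "T"), sum(lengths), replace = TRUE)
  grp <- rep(seq_along(lengths), lengths)
  out <- vapply(split(chars, grp), paste, character(1), collapse = "")
  unname(out[as.character(seq_along(lengths))])
}

#' Reverse-translate peptides to coding DNA
#'
#' Picks a random synonymous codon for each residue (standard genetic code,
#' no stop codon appended), so identical peptides generally receive
#' different nucleotide sequences -- as homologous genes in distinct genomes
#' do.
#'
#' @param peptides `AAStringSet` or character vector of peptide sequences.
#' @return `DNAStringSet` of the same length and names.
#' @export
reverse_translate <- function(peptides) {
  pep <- as.character(peptides)
  if (length(pep) == 0) return(Biostrings::DNAStringSet())
  cb <- codons_by_aa()
  ncods <- lengths(cb)
  codmat <- matrix("", nrow = length(cb), ncol = max(ncods))
  for (i in seq_along(cb)) codmat[i, seq_len(ncods[i])] <- cb[[i]]
  chars <- strsplit(pep, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  ai <- match(flat, names(cb))
  if (anyNA(ai)) input_error("non-standard amino acid in peptide input")
  pick <- floor(runif(length(flat)) * ncods[ai]) + 1
  codon <- codmat[cbind(ai, pick)]
  grp <- rep(seq_along(lens), lens)
  nt <- vapply(split(codon, grp), paste, character(1), collapse = "")
  nt <- unname(nt[as.character(seq_along(lens))])
  out <- Biostrings::DNAStringSet(nt)
  names(out) <- names(peptides)
  out
}

#' Simulation parameters
#'
#' Defaults describe the simulated study conditions: communities of 20
#' genomes with per-genome depth drawn log-normally (median 5x, 1 log10 SD,
#' capped at 100x), paired-end 250 bp reads from 1000 +/- 300 bp fragments,
#' and a reference set in which most proteins carry conserved cores shared
#' (identically) with reference-only homologs, so that reads genuinely
#' multi-map, plus short-domain decoys recruiting reads over only a small
#' part of their length.
#'
#' @param n_genomes Number of genomes per community.
#' @param cds_per_genome CDS per genome (with ~300 aa CDS and short spacers,
#'   250 gives ~250 kb genomes, ~5 Mb per 20-genome community).
#' @param cds_length_range Uniform range of CDS lengths (amino acids).
#' @param spacer_range Uniform range of intergenic spacer lengths (bp).
#' @param depth_mean Depth scale (x); by default the log-normal's median
#'   (`10^mu = depth_mean`); set `depth_mean_is = "mean"` to interpret it as
#'   the arithmetic mean instead.
#' @param depth_sd SD of the underlying normal in log10 units.
#' @param depth_max Depth cap (x).
#' @param depth_mean_is Whether `depth_mean` is the median or the mean of
#'   the log-normal.
#' @param read_length Read length (bp).
#' @param frag_mean,frag_sd Fragment length distribution (bp); fragments are
#'   truncated to `[read_length, sequence length]`.
#' @param error_rate Per-base substitution rate.
#' @param conserved_fraction Fraction of community CDS whose core is shared
#'   with reference-only homologs.
#' @param paired_fraction Of the conserved CDS, the fraction that occur as
#'   core-sharing pairs placed in two community genomes.
#' @param core_fraction Fraction of a conserved CDS's length occupied by the
#'   shared core (the termini are member-specific).
#' @param n_orthologs Reference-only full-length homologs per family.
#' @param n_domain_decoys Reference-only decoys per family sharing only a
#'   `domain_length` slice of the core.
#' @param domain_length Length (aa) of the short shared domain in decoys.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_genomes = 20, cds_per_genome = 250,
                       cds_length_range = c(150, 450),
                       spacer_range = c(50, 150),
                       depth_mean = 5, depth_sd = 1, depth_max = 100,
                       depth_mean_is = c("median", "mean"),
                       read_length = 250, frag_mean = 1000, frag_sd = 300,
                       error_rate = 0,
                       conserved_fraction = 0.9, paired_fraction = 0.1,
                       core_fraction = 0.8, n_orthologs = 2,
                       n_domain_decoys = 1, domain_length = 70) {
  depth_mean_is <- match.arg(depth_mean_is)
  p <- list(n_genomes = as.integer(n_genomes),
            cds_per_genome = as.integer(cds_per_genome),
            cds_length_range = as.integer(cds_length_range),
            spacer_range = as.integer(spacer_range),
            depth_mean = depth_mean, depth_sd = depth_sd,
            depth_max = depth_max, depth_mean_is = depth_mean_is,
            read_length = as.integer(read_length), frag_mean = frag_mean,
            frag_sd = frag_sd, error_rate = error_rate,
            conserved_fraction = conserved_fraction,
            paired_fraction = paired_fraction,
            core_fraction = core_fraction,
            n_orthologs = as.integer(n_orthologs),
            n_domain_decoys = as.integer(n_domain_decoys),
            domain_length = as.integer(domain_length))
  if (any(c(p$n_genomes, p$cds_per_genome, p$depth_mean, p$depth_max,
            p$read_length, p$frag_mean, p$frag_sd) <= 0) ||
      p$depth_sd < 0 || p$error_rate < 0 || p$error_rate >= 1) {
    input_error("simulation parameters must be positive (error_rate in [0,1))")
  }
  if (p$read_length > p$frag_mean) {
    warning("read_length exceeds frag_mean; mates will largely overlap")
  }
  structure(p, class = "sim_params")
}

#' Draw per-genome sequencing depths
#'
#' `depth_i = min(depth_max, 10^N(mu, depth_sd))` with `10^mu = depth_mean`
#' (median convention; see [sim_params()]). Deterministic given `seed`.
#'
#' @param n Number of genomes.
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed; when NULL the current RNG stream is
#'   used.
#' @return Named numeric vector of depths in (0, depth_max].
#' @export
sample_depths <- function(n, params = sim_params(), seed = NULL) {
  if (n < 1) input_error("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  mu <- if (params$depth_mean_is == "median") {
    log10(params$depth_mean)
  } else {
    # arithmetic mean of a log10-normal: mean = 10^(mu + sd^2 * ln(10) / 2)
    log10(params$depth_mean) - params$depth_sd^2 * log(10) / 2
  }
  d <- pmin(params$depth_max, 10^rnorm(n, mu, params$depth_sd))
  setNames(d, sprintf("g%03d", seq_len(n)))
}

#' Generate a family of homologous peptides sharing a conserved domain
#'
#' Each member is `flank + domain + flank`: the domain (length
#' `domain_length`) is identical across members, while the flanks (total
#' length `unique_length`, split evenly around the domain) are sampled
#' independently per member, giving low pairwise identity outside the
#' domain (members whose flank identity exceeds `divergence` are resampled).
#'
#' @param n_members Number of family members (>= 2).
#' @param domain_length Conserved domain length (aa); 0 gives pairwise
#'   dissimilar sequences.
#' @param unique_length Total member-specific flank length (aa).
#' @param divergence Maximum tolerated pairwise flank identity (fraction).
#' @param seed Optional integer seed.
#' @return Named `AAStringSet` (`member01`, `member02`, ...).
#' @export
make_homolog_family <- function(n_members, domain_length, unique_length,
                                divergence = 0.1, seed = NULL) {
  if (n_members < 2) input_error("n_members must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  left <- ceiling(unique_length / 2)
  right <- unique_length - left
  domain <- if (domain_length > 0) rand_aa_strings(domain_length) else ""
  lf <- rand_aa_strings(rep(left, n_members))
  rf <- rand_aa_strings(rep(right, n_members))
  if (unique_length > 0) {
    flank_id <- function(a, b) {
      mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    }
    for (tries in 1:25) {
      ok <- TRUE
      for (i in seq_len(n_members - 1)) {
        for (j in (i + 1):n_members) {
          if (flank_id(paste0(lf[i], rf[i]), paste0(lf[j], rf[j])) >
              divergence) {
            lf[j] <- rand_aa_strings(left)
            rf[j] <- if (right > 0) rand_aa_strings(right) else ""
            ok <- FALSE
          }
        }
      }
      if (ok) break
    }
  }
  out <- Biostrings::AAStringSet(paste0(lf, domain, rf))
  names(out) <- sprintf("member%02d", seq_len(n_members))
  out
}

#' Simulate a synthetic microbial community with known CDS content
#'
#' Builds `n_genomes` genomes of protein-coding genes separated by random
#' intergenic spacers, assigns each genome a log-normal sequencing depth,
#' and constructs a reference peptide database containing every community
#' CDS plus, for each "conserved" CDS family, reference-only full-length
#' homologs (identical conserved core, member-specific termini) and
#' short-domain decoys. See [sim_params()] for the knobs.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed (the whole community is a deterministic function
#'   of it).
#' @return Object of class `community_sim` with elements `genomes`
#'   (`DNAStringSet`), `cds_peptides` (community CDS, `AAStringSet`),
#'   `reference` (full reference DB incl. decoys), `cds_info` (data.table:
#'   cds_id, genome, family, category, length_aa, start, end, depth),
#'   `genome_depths`, `params`, `seed`.
#' @export
simulate_community <- function(params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  n_cds <- p$n_genomes * p$cds_per_genome
  genome_of <- rep(seq_len(p$n_genomes), each = p$cds_per_genome)
  len_aa <- sample(p$cds_length_range[1]:p$cds_length_range[2], n_cds,
                   replace = TRUE)

  category <- rep("unique", n_cds)
  n_conserved <- round(p$conserved_fraction * n_cds)
  cons_idx <- sort(sample.int(n_cds, n_conserved))
  category[cons_idx] <- "conserved"
  n_pairs <- floor(p$paired_fraction * n_conserved / 2)
  family <- sprintf("f%05d", seq_len(n_cds))
  if (n_pairs > 0) {
    pair_slots <- matrix(sample(cons_idx, 2 * n_pairs), ncol = 2)
    category[pair_slots] <- "paired"
    family[pair_slots[, 2]] <- family[pair_slots[, 1]]
    len_aa[pair_slots[, 2]] <- len_aa[pair_slots[, 1]]
  }

  cds_id <- sprintf("g%03d_c%04d", genome_of,
                    sequence(rep(p$cds_per_genome, p$n_genomes)))

  # conserved cores, one per family of conserved/paired CDS
  fam_rows <- which(category != "unique")
  fam_tab <- data.table(idx = fam_rows, family = family[fam_rows],
                        len = len_aa[fam_rows])
  fams <- fam_tab[!duplicated(family)]
  fams[, core_len := pmax(1L, as.integer(round(p$core_fraction * len)))]
  cores <- rand_aa_strings(fams$core_len)
  fams[, core := cores]
  setkey(fams, family)

  # community peptides
  pep <- character(n_cds)
  uniq_rows <- which(category == "unique")
  pep[uniq_rows] <- rand_aa_strings(len_aa[uniq_rows])
  if (length(fam_rows)) {
    fam_key <- family[fam_rows]
    fi <- fams[J(fam_key)]
    t1 <- as.integer(floor((len_aa[fam_rows] - fi$core_len) / 2))
    t2 <- len_aa[fam_rows] - fi$core_len - t1
    pep[fam_rows] <- paste0(rand_aa_strings(t1), fi$core, rand_aa_strings(t2))
  }

  # reference-only homologs and domain decoys, per family
  ref_extra <- character(0)
  if (nrow(fams) > 0 && (p$n_orthologs > 0 || p$n_domain_decoys > 0)) {
    L <- fams$len
    cl <- fams$core_len
    orth <- list()
    if (p$n_orthologs > 0) {
      for (j in seq_len(p$n_orthologs)) {
        t1 <- as.integer(floor((L - cl) / 2))
        t2 <- L - cl - t1
        o <- paste0(rand_aa_strings(t1), fams$core, rand_aa_strings(t2))
        names(o) <- sprintf("%s_orth%d", fams$family, j)
        orth[[j]] <- o
      }
    }
    dec <- list()
    if (p$n_domain_decoys > 0) {
      dlen <- pmin(p$domain_length, cl)
      dstart <- pmax(1L, as.integer(floor((cl - dlen) / 2)) + 1L)
      slice <- substr(fams$core, dstart, dstart + dlen - 1L)
      for (j in seq_len(p$n_domain_decoys)) {
        l1 <- as.integer(floor((L - dlen) / 2))
        l2 <- L - dlen - l1
        d <- paste0(rand_aa_strings(l1), slice, rand_aa_strings(l2))
        names(d) <- sprintf("%s_dom%d", fams$family, j)
        dec[[j]] <- d
      }
    }
    ref_extra <- c(unlist(orth), unlist(dec))
  }

  # nucleotide genomes: spacer cds spacer cds ... spacer
  nt <- as.character(reverse_translate(pep))
  info <- data.table(cds_id = cds_id, genome = sprintf("g%03d", genome_of),
                     family = family, category = category,
                     length_aa = len_aa, length_nt = nchar(nt))
  genomes <- character(p$n_genomes)
  starts <- integer(n_cds)
  for (g in seq_len(p$n_genomes)) {
    rows <- which(genome_of == g)
    spacers <- rand_dna_strings(
      sample(p$spacer_range[1]:p$spacer_range[2], length(rows) + 1,
             replace = TRUE))
    pieces <- character(2 * length(rows) + 1)
    pieces[seq(1, length(pieces), by = 2)] <- spacers
    pieces[seq(2, length(pieces), by = 2)] <- nt[rows]
    widths <- nchar(pieces)
    offs <- cumsum(c(0, widths[-length(widths)]))
    starts[rows] <- offs[seq(2, length(pieces), by = 2)] + 1L
    genomes[g] <- paste(pieces, collapse = "")
  }
  info[, start := starts]
  info[, end := start + length_nt - 1L]

  depths <- sample_depths(p$n_genomes, p)
  info[, depth := depths[genome]]

  genome_set <- Biostrings::DNAStringSet(genomes)
  names(genome_set) <- sprintf("g%03d", seq_len(p$n_genomes))
  cds_set <- Biostrings::AAStringSet(pep)
  names(cds_set) <- cds_id
  reference <- Biostrings::AAStringSet(c(setNames(pep, cds_id), ref_extra))

  structure(list(genomes = genome_set, cds_peptides = cds_set,
                 reference = reference, cds_info = info,
                 genome_depths = depths, params = p, seed = seed),
            class = "community_sim")
}

#' @export
print.community_sim <- function(x, ...) {
  cat(sprintf(
    "community_sim: %d genomes (%.2f Mb), %d CDS, %d reference peptides\n",
    length(x$genomes), sum(Biostrings::width(x$genomes)) / 1e6,
    nrow(x$cds_info), length(x$reference)))
  cat(sprintf("  genome depths: median %.2fx, range %.2f-%.2fx\n",
              median(x$genome_depths), min(x$genome_depths),
              max(x$genome_depths)))
  invisible(x)
}

# Draw paired-end reads from one sequence (current RNG stream). Returns
# mate-1 and raw mate-2 substrings (mate 2 not yet reverse-complemented)
# plus fragment coordinates.
sim_pairs_from_seq <- function(seq_chr, n_pairs, p) {
  len <- nchar(seq_chr)
  rl <- min(p$read_length, len)
  frag <- pmax(rl, pmin(len, round(rnorm(n_pairs, p$frag_mean, p$frag_sd))))
  start <- 1L + floor(runif(n_pairs) * (len - frag + 1))
  m1 <- substring(seq_chr, start, start + rl - 1L)
  m2 <- substring(seq_chr, start + frag - rl, start + frag - 1L)
  list(m1 = m1, m2 = m2, start = as.integer(start),
       end = as.integer(start + frag - 1L), read_length = rl)
}

add_substitutions <- function(chars, rate) {
  if (rate <= 0) return(chars)
  nerr <- rbinom(length(chars), nchar(chars), rate)
  for (i in which(nerr > 0)) {
    pos <- sample.int(nchar(chars[i]), nerr[i])
    for (pp in pos) {
      orig <- substr(chars[i], pp, pp)
      substr(chars[i], pp, pp) <- sample(setdiff(c("A", "C", "G", "T"), orig),
                                         1)
    }
  }
  chars
}

finish_read_sim <- function(m1, m2raw, ids, origins, p) {
  m1 <- add_substitutions(m1, p$error_rate)
  m2raw <- add_substitutions(m2raw, p$error_rate)
  fwd <- Biostrings::DNAStringSet(m1)
  rev <- Biostrings::reverseComplement(Biostrings::DNAStringSet(m2raw))
  names(fwd) <- ids
  names(rev) <- ids
  structure(list(fwd = fwd, rev = rev, origins = origins, params = p),
            class = "read_sim")
}

#' Simulate paired-end reads from a community
#'
#' The number of read pairs per genome is `round(depth * length /
#' (2 * read_length))`; fragment lengths are normal
#' (`frag_mean` +/- `frag_sd`), truncated to `[read_length, genome
#' length]`; mate 2 is reverse-complemented. Each pair is labelled with its
#' true origin CDS -- the CDS with the largest total overlap with the two
#' mates (ties to the leftmost CDS); pairs overlapping no CDS by at least
#' one codon get `NA`.
#'
#' @param community A `community_sim` from [simulate_community()].
#' @param seed Optional integer seed.
#' @param reads_per_genome Optional fixed pair count per genome, overriding
#'   the depth model.
#' @return Object of class `read_sim`: `fwd`/`rev` (`DNAStringSet`, names =
#'   pair ids), `origins` (data.table read_id, cds_id), `params`.
#' @export
simulate_reads <- function(community, seed = NULL, reads_per_genome = NULL) {
  stopifnot(inherits(community, "community_sim"))
  if (!is.null(seed)) set.seed(seed)
  p <- community$params
  seqs <- as.character(community$genomes)
  lens <- nchar(seqs)
  n_pairs <- if (is.null(reads_per_genome)) {
    as.integer(round(community$genome_depths * lens / (2 * p$read_length)))
  } else {
    rep_len(as.integer(reads_per_genome), length(seqs))
  }
  m1 <- vector("list", length(seqs))
  m2 <- vector("list", length(seqs))
  ids <- vector("list", length(seqs))
  orig <- vector("list", length(seqs))
  for (g in seq_along(seqs)) {
    if (n_pairs[g] == 0) next
    gid <- names(community$genomes)[g]
    pr <- sim_pairs_from_seq(seqs[g], n_pairs[g], p)
    pid <- sprintf("%s_p%06d", gid, seq_len(n_pairs[g]))
    rl <- pr$read_length
    cds <- community$cds_info[genome == gid]
    mr1 <- IRanges::IRanges(pr$start, pr$start + rl - 1L)
    mr2 <- IRanges::IRanges(pr$end - rl + 1L, pr$end)
    cr <- IRanges::IRanges(cds$start, cds$end)
    ov <- rbind(overlap_table(mr1, cr), overlap_table(mr2, cr))
    lab <- rep(NA_character_, n_pairs[g])
    if (nrow(ov)) {
      ov <- ov[, .(w = sum(w)), by = .(pair, cds)]
      setorder(ov, pair, -w, cds)
      top <- ov[!duplicated(pair)][w >= 3]
      lab[top$pair] <- cds$cds_id[top$cds]
    }
    m1[[g]] <- pr$m1
    m2[[g]] <- pr$m2
    ids[[g]] <- pid
    orig[[g]] <- data.table(read_id = pid, cds_id = lab)
  }
  finish_read_sim(unlist(m1), unlist(m2), unlist(ids),
                  rbindlist(orig), p)
}

overlap_table <- function(reads, cds) {
  hits <- IRanges::findOverlaps(reads, cds)
  if (length(hits) == 0) {
    return(data.table(pair = integer(), cds = integer(), w = integer()))
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  w <- IRanges::width(IRanges::pintersect(reads[qi], cds[si]))
  data.table(pair = qi, cds = si, w = w)
}

#' Simulate a fixed number of read pairs from each CDS
#'
#' Companion to [simulate_reads()] for fixtures where reads are drawn from
#' CDS nucleotide sequences directly (every pair's origin is its source
#' CDS).
#'
#' @param cds_nt Named `DNAStringSet` of CDS nucleotide sequences.
#' @param reads_per_cds Pairs to draw from each CDS.
#' @param params A [sim_params()] object (read/fragment geometry, errors).
#' @param seed Optional integer seed.
#' @return A `read_sim` object.
#' @export
simulate_cds_reads <- function(cds_nt, reads_per_cds,
                               params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  seqs <- as.character(cds_nt)
  m1 <- m2 <- ids <- vector("list", length(seqs))
  orig <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    sid <- names(cds_nt)[i]
    pr <- sim_pairs_from_seq(seqs[i], reads_per_cds, p)
    pid <- sprintf("%s_p%04d", sid, seq_len(reads_per_cds))
    m1[[i]] <- pr$m1
    m2[[i]] <- pr$m2
    ids[[i]] <- pid
    orig[[i]] <- data.table(read_id = pid, cds_id = sid)
  }
  finish_read_sim(unlist(m1), unlist(m2), unlist(ids), rbindlist(orig), p)
}

#' @export
print.read_sim <- function(x, ...) {
  cat(sprintf("read_sim: %d read pairs (%d labelled with an origin CDS)\n",
              length(x$fwd), sum(!is.na(x$origins$cds_id))))
  invisible(x)
}

#' Write simulated reads as split paired FASTQ
#'
#' @param reads A `read_sim` object.
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` (`.gz` appended when `gzip`).
#' @param gzip Compress output.
#' @return The two file paths, invisibly.
#' @export
write_reads <- function(reads, prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- paste0(prefix, "_1", ext)
  p2 <- paste0(prefix, "_2", ext)
  fwd <- reads$fwd
  rev <- reads$rev
  names(fwd) <- paste0(names(fwd), "/1")
  names(rev) <- paste0(names(rev), "/2")
  q1 <- Biostrings::PhredQuality(strrep("I", Biostrings::width(fwd)))
  q2 <- Biostrings::PhredQuality(strrep("I", Biostrings::width(rev)))
  Biostrings::writeXStringSet(fwd, p1, format = "fastq", qualities = q1,
                              compress = gzip)
  Biostrings::writeXStringSet(rev, p2, format = "fastq", qualities = q2,
                              compress = gzip)
  invisible(c(p1, p2))
}
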