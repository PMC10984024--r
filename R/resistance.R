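#' Transcript model from a GFF3 annotation
#'
#' Collects the ordered CDS intervals of one transcript. CDS lengths must
#' sum to a multiple of three; intervals may not overlap.
#'
#' @param path GFF3 path.
#' @param transcript_id transcript identifier (matched against the CDS
#'   `Parent` attribute and the mRNA `ID`).
#' @return List with `transcript_id`, `contig`, `strand`, `cds` (tibble
#'   `start`, `end`, ordered in translation order).
#' @export
read_transcript_model <- function(path, transcript_id) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  parent <- vapply(cds$Parent, function(p) paste(p, collapse = ","), character(1))
  cds <- cds[grepl(transcript_id, parent, fixed = TRUE)]
  if (!length(cds)) abort(paste0("no CDS found for transcript ", transcript_id))
  tab <- tibble(
    contig = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds),
    strand = as.character(GenomicRanges::strand(cds))
  ) %>% arrange(.data$start)
  if (length(unique(tab$contig)) != 1) abort("CDS spans multiple contigs")
  strand <- unique(tab$strand)
  if (length(strand) != 1) abort("CDS mixes strands")
  if (any(tab$start[-1] <= tab$end[-nrow(tab)])) abort("CDS intervals overlap")
  if (sum(tab$end - tab$start + 1) %% 3 != 0) {
    abort("CDS lengths do not sum to a multiple of 3")
  }
  list(
    transcript_id = transcript_id,
    contig = tab$contig[1],
    strand = strand,
    cds = tab %>% select("start", "end")
  )
}

#' In-memory transcript model constructor (mainly for tests/simulation)
#'
#' @param transcript_id transcript label.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param cds tibble with `start`, `end` (1-based inclusive, genomic order).
#' @return Transcript model list as from [read_transcript_model()].
#' @export
transcript_model <- function(transcript_id, contig, strand, cds) {
  cds <- as_tibble(cds) %>% arrange(.data$start)
  if (sum(cds$end - cds$start + 1) %% 3 != 0) {
    abort("CDS lengths do not sum to a multiple of 3")
  }
  list(transcript_id = transcript_id, contig = contig, strand = strand,
       cds = cds)
}

#' Predict amino-acid changes for SNPs against a transcript
#'
#' Maps each variant into the coding sequence (strand-aware, standard
#' genetic code via Biostrings), builds the reference codon from the
#' genome sequence and substitutes the alternate base to classify the
#' change as non-synonymous, synonymous or noncoding. Reference alleles
#' must match the genome sequence inside the CDS. Multi-nucleotide codon
#' changes are out of scope: each SNP is evaluated against the reference
#' codon alone.
#'
#' @param variants tibble with `contig`, `pos`, `ref`, `alt`.
#' @param transcript model from [read_transcript_model()] /
#'   [transcript_model()].
#' @param genome a named `Biostrings::DNAStringSet` (e.g. from
#'   `Biostrings::readDNAStringSet`) containing the transcript's contig.
#' @return Tibble: input columns plus `effect` (`"non-synonymous"`,
#'   `"synonymous"`, `"noncoding"`), `codon_number`, `ref_aa`, `alt_aa`,
#'   `substitution` (e.g. `"L995F"`, `NA` unless non-synonymous).
#' @export
annotate_aa_changes <- function(variants, transcript, genome) {
  ctg <- transcript$contig
  if (!ctg %in% names(genome)) abort(paste0("contig missing from genome: ", ctg))
  seq <- genome[[ctg]]
  # genomic positions of the coding sequence in translation order
  gpos <- unlist(lapply(seq_len(nrow(transcript$cds)), function(i) {
    transcript$cds$start[i]:transcript$cds$end[i]
  }))
  if (transcript$strand == "-") gpos <- rev(gpos)
  cds_index <- stats::setNames(seq_along(gpos), gpos)
  cds_seq <- seq[gpos]
  if (transcript$strand == "-") {
    cds_seq <- Biostrings::complement(cds_seq)
  }
  cds_chars <- strsplit(as.character(cds_seq), "")[[1]]
  code <- Biostrings::GENETIC_CODE
  out <- variants %>%
    mutate(effect = "noncoding", codon_number = NA_integer_,
           ref_aa = NA_character_, alt_aa = NA_character_,
           substitution = NA_character_)
  in_cds <- out$contig == ctg & as.character(out$pos) %in% names(cds_index)
  for (i in which(in_cds)) {
    ci <- cds_index[[as.character(out$pos[i])]]
    ref_base <- out$ref[i]
    alt_base <- out$alt[i]
    genome_base <- as.character(seq[out$pos[i]])
    if (genome_base != ref_base) {
      abort(paste0("reference allele mismatch at ", ctg, ":", out$pos[i]))
    }
    if (transcript$strand == "-") {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      ref_base <- comp[[ref_base]]
      alt_base <- comp[[alt_base]]
    }
    codon_num <- (ci - 1L) %/% 3L + 1L
    within <- (ci - 1L) %% 3L + 1L
    codon <- cds_chars[(codon_num - 1L) * 3L + 1:3]
    stopifnot(codon[within] == ref_base)
    alt_codon <- codon
    alt_codon[within] <- alt_base
    ref_aa <- code[[paste(codon, collapse = "")]]
    alt_aa <- code[[paste(alt_codon, collapse = "")]]
    out$codon_number[i] <- codon_num
    out$ref_aa[i] <- ref_aa
    out$alt_aa[i] <- alt_aa
    if (ref_aa == alt_aa) {
      out$effect[i] <- "synonymous"
    } else {
      out$effect[i] <- "non-synonymous"
      out$substitution[i] <- paste0(ref_aa, codon_num, alt_aa)
    }
  }
  out
}

#' Per-cohort amino-acid substitution frequencies
#'
#' Alternate-allele frequencies (over called alleles) per cohort for
#' non-synonymous variants, aggregated per amino-acid substitution (two
#' SNPs causing the same change have their frequencies summed). Only
#' substitutions whose frequency exceeds `retain_min` in at least one
#' cohort are retained -- the sequencing-error guard used in the study.
#' Per-variant frequencies are available in the `per_variant` attribute.
#'
#' @param annotated tibble from [annotate_aa_changes()].
#' @param g a `geno` object aligned with `annotated` rows by
#'   (`contig`, `pos`).
#' @param meta metadata tibble (`sample_id`, `cohort`).
#' @param retain_min retention threshold (default 0.05, strict `>`).
#' @return Tibble `substitution`, `codon_number`, `cohort`, `frequency`.
#' @export
cohort_substitution_frequencies <- function(annotated, g, meta,
                                            retain_min = 0.05) {
  nonsyn <- annotated %>% filter(.data$effect == "non-synonymous")
  if (!nrow(nonsyn)) {
    return(tibble(substitution = character(), codon_number = integer(),
                  cohort = character(), frequency = double()))
  }
  key_g <- paste(g$variants$contig, g$variants$pos)
  per_var <- purrr::map_dfr(unique(meta$cohort), function(coh) {
    ids <- meta$sample_id[meta$cohort == coh]
    ac <- allele_counts(g, ids)
    hit <- match(paste(nonsyn$contig, nonsyn$pos), paste(ac$contig, ac$pos))
    tibble(
      substitution = nonsyn$substitution,
      codon_number = nonsyn$codon_number,
      contig = nonsyn$contig,
      pos = nonsyn$pos,
      cohort = coh,
      frequency = allele_freq(ac)[hit]
    )
  })
  agg <- per_var %>%
    group_by(.data$substitution, .data$codon_number, .data$cohort) %>%
    summarise(frequency = sum(.data$frequency, na.rm = TRUE), .groups = "drop")
  keep <- agg %>%
    group_by(.data$substitution) %>%
    summarise(mx = max(.data$frequency, na.rm = TRUE), .groups = "drop") %>%
    filter(.data$mx > retain_min) %>%
    pull(.data$substitution)
  out <- agg %>% filter(.data$substitution %in% keep) %>%
    arrange(.data$codon_number, .data$substitution, .data$cohort)
  attr(out, "per_variant") <- per_var %>%
    filter(.data$substitution %in% keep)
  out
}
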