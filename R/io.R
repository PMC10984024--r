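#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (via vcfR) into a [new_geno()] container. Only the
#' GT field is used. Multiallelic records are dropped when
#' `drop_multiallelic` is TRUE (the default), otherwise an error is raised
#' when one is encountered. Phased and unphased separators are accepted;
#' phase is not retained here (see [read_haplotypes()] for phased input).
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param region optional `"contig:start-end"` string to subset on read.
#' @param drop_multiallelic drop records with more than one ALT allele.
#' @return A `geno` object. The FILTER column is mapped to
#'   `pass_site_filter` (`PASS` or `.` count as passing).
#' @export
read_vcf <- function(path, region = NULL, drop_multiallelic = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) abort("VCF contains no records")
  gt_raw <- v@gt
  if (is.null(gt_raw) || !"FORMAT" %in% colnames(gt_raw)) {
    abort("VCF has no genotype (GT) data")
  }
  samples <- setdiff(colnames(gt_raw), "FORMAT")
  if (!all(grepl("(^|:)GT(:|$)", gt_raw[, "FORMAT"]))) {
    abort("every record must carry a GT field")
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  keep <- rep(TRUE, nrow(fix))
  if (any(multi)) {
    if (!drop_multiallelic) abort("multiallelic records present; set drop_multiallelic = TRUE")
    keep <- !multi
  }
  variants <- tibble(
    contig = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    pass_site_filter = fix$FILTER[keep] %in% c("PASS", ".", NA)
  )
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) abort("`region` must look like contig:start-end")
    sel <- variants$contig == m[2] &
      variants$pos >= as.integer(m[3]) & variants$pos <= as.integer(m[4])
  } else {
    sel <- rep(TRUE, nrow(variants))
  }
  gt <- gt_raw[keep, samples, drop = FALSE][sel, , drop = FALSE]
  variants <- variants[sel, , drop = FALSE]
  # GT is the first colon-separated field; alleles split on / or |
  gt_field <- sub(":.*$", "", gt)
  a1 <- suppressWarnings(as.integer(sub("^([0-9.]+)[/|].*$", "\\1", gt_field)))
  a2 <- suppressWarnings(as.integer(sub("^[0-9.]+[/|]([0-9.]+)$", "\\1", gt_field)))
  L <- nrow(variants)
  N <- length(samples)
  calls <- array(NA_integer_, dim = c(L, N, 2))
  calls[, , 1] <- matrix(a1, nrow = L)
  calls[, , 2] <- matrix(a2, nrow = L)
  if (any(calls > 1L, na.rm = TRUE)) abort("allele indices > 1 after multiallelic handling")
  new_geno(calls, variants, samples)
}

#' Write a genotype container to a VCF file
#'
#' Emits a minimal VCF 4.2 with unphased GT-only genotypes; the FILTER
#' column records `PASS` or `FAIL` from `pass_site_filter`. Round-trips
#' through [read_vcf()] exactly (calls, positions, sample order).
#'
#' @param g a `geno` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  al <- function(x) ifelse(is.na(x), ".", as.character(x))
  gt <- matrix(
    paste0(al(g$calls[, , 1]), "/", al(g$calls[, , 2])),
    nrow = n_variants(g)
  )
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(g$variants$contig), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  )
  body <- paste(
    g$variants$contig, g$variants$pos, ".",
    g$variants$ref, g$variants$alt, ".",
    ifelse(g$variants$pass_site_filter, "PASS", "FAIL"), ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phased haplotypes from a VCF file
#'
#' Requires every genotype to be phased (`|` separator) and fully called;
#' returns a variants x (2 x samples) binary haplotype matrix.
#'
#' @param path path to a VCF with phased GT.
#' @return A list with `haps` (integer matrix variants x haplotypes),
#'   `positions`, `contig`, and `haplotype_ids` (`sample_a`/`sample_b`).
#' @export
read_haplotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- setdiff(colnames(v@gt), "FORMAT")
  gt <- sub(":.*$", "", v@gt[, samples, drop = FALSE])
  if (any(!grepl("^[01]\\|[01]$", gt))) {
    abort("haplotype input must be fully phased (|) and called")
  }
  a1 <- as.integer(substr(gt, 1, 1))
  a2 <- as.integer(substr(gt, 3, 3))
  L <- nrow(gt)
  haps <- matrix(NA_integer_, nrow = L, ncol = 2 * length(samples))
  haps[, seq(1, 2 * length(samples), by = 2)] <- matrix(a1, nrow = L)
  haps[, seq(2, 2 * length(samples), by = 2)] <- matrix(a2, nrow = L)
  colnames(haps) <- paste0(rep(samples, each = 2), c("_a", "_b"))
  list(
    haps = haps,
    positions = as.integer(fix$POS),
    contig = fix$CHROM[1],
    haplotype_ids = colnames(haps)
  )
}

#' Read a genome accessibility mask from BED
#'
#' BED intervals (0-based half-open) are converted to per-position logical
#' accessibility vectors (1-based inclusive) per contig.
#'
#' @param path path to a BED file of accessible intervals.
#' @param contig_lengths named integer vector giving each contig's length.
#' @return Named list of logical vectors, one per contig.
#' @export
read_bed_mask <- function(path, contig_lengths) {
  bed <- readr::read_tsv(
    path,
    col_names = c("contig", "start", "end"),
    col_types = "cii",
    comment = "#", progress = FALSE
  )
  mask <- lapply(contig_lengths, function(len) rep(FALSE, len))
  for (i in seq_len(nrow(bed))) {
    ctg <- bed$contig[i]
    if (!ctg %in% names(mask)) abort(paste0("BED contig not in contig_lengths: ", ctg))
    from <- bed$start[i] + 1L   # 0-based half-open -> 1-based inclusive
    to <- min(bed$end[i], contig_lengths[[ctg]])
    if (to >= from) mask[[ctg]][from:to] <- TRUE
  }
  mask
}

#' Read a sample metadata table
#'
#' Tab-separated with header; required columns `sample_id` and `cohort`,
#' optional `country`, `site`, `sex` (F/M/unknown) and `year`.
#'
#' @param path path to a TSV file.
#' @return A tibble with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  req <- c("sample_id", "cohort")
  if (!all(req %in% names(meta))) {
    abort("sample metadata needs columns sample_id and cohort")
  }
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample_id in metadata")
  if (!"sex" %in% names(meta)) meta$sex <- "unknown"
  as_tibble(meta)
}

#' Read gene features from a GFF3 annotation
#'
#' @param path path to a GFF3 file.
#' @param feature feature type to keep (default `"gene"`).
#' @return Tibble with `gene_id`, `contig`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates, as in GFF3).
#' @export
read_gff_genes <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  tibble(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}
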