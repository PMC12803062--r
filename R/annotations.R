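#' @title Gene annotations, exclusion regions, and variant filters
#' @description Readers for BED/GFF3 gene annotations and BED exclusion lists,
#' the autosome/gene-window/exclusion variant filter, and SNP-to-gene
#' assignment. Coordinates are 1-based inclusive internally; BED input is
#' converted from 0-based half-open on read (rtracklayer does this).
#' Chromosome names are compared after stripping any `chr` prefix, so `chr1`
#' and `1` match.
#' @name annotations
NULL

.norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read gene annotations from BED or GFF3
#'
#' BED files use the `name` column (BED6) as the gene id; GFF3 files are
#' restricted to `gene`-type features and the id is taken from the `ID`,
#' `gene_id` or `Name` attribute, whichever exists first.
#'
#' @param path annotation file; format inferred from the extension
#'   (`.bed` vs `.gff`/`.gff3`) unless `format` is given.
#' @param format `"bed"` or `"gff3"`, overriding extension-based detection.
#' @return tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates; strand `+` or `-`, unstranded features
#'   are treated as `+`).
#' @export
read_gene_annotations <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[as.character(gr$type) == "gene"]
    }
    md <- S4Vectors::mcols(gr)
    id_col <- intersect(c("ID", "gene_id", "Name"), names(md))[1]
    if (is.na(id_col)) stop("GFF3 gene features carry no ID/gene_id/Name attribute")
    ids <- as.character(md[[id_col]])
  } else {
    ids <- if ("name" %in% names(S4Vectors::mcols(gr))) {
      as.character(gr$name)
    } else {
      paste0("gene_", seq_along(gr))
    }
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  tibble::tibble(
    gene_id = ids,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand
  )
}

#' Read an exclusion-region list (BED3)
#'
#' The regions stand in for sites with high sequence identity to the sex
#' chromosomes (e.g. from an external homology search); SNPs inside any
#' region are dropped by [apply_variant_filters()].
#'
#' @param path BED file of regions to exclude.
#' @return tibble with columns `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_exclusion_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr)
  )
}

# Gene search windows: the gene body extended by `upstream` bp beyond the
# transcription start (5' end as given by the strand).
.gene_windows <- function(genes, upstream) {
  minus <- genes$strand == "-"
  tibble::tibble(
    gene_id = genes$gene_id,
    chrom = .norm_chrom(genes$chrom),
    start = ifelse(minus, genes$start, pmax(1L, genes$start - upstream)),
    end = ifelse(minus, genes$end + upstream, genes$end)
  )
}

.overlap_hits <- function(chrom, pos, win) {
  snp_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  win_gr <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$start, win$end))
  # disjoint seqlevels are handled by the callers' own diagnostics
  suppressWarnings(GenomicRanges::findOverlaps(snp_gr, win_gr))
}

#' Filter SNPs to autosomal, gene-proximal, non-excluded sites
#'
#' Retains exactly the SNPs that (i) lie on an allowed chromosome (default:
#' autosomes 1-22), (ii) fall within at least one gene body or its
#' strand-aware upstream window, and (iii) overlap no exclusion region.
#' Row order is preserved and the operation is idempotent. Per-stage
#' retention counts are attached as the `"filter_log"` attribute.
#'
#' @param ds a [study_dataset()].
#' @param genes gene annotation tibble from [read_gene_annotations()].
#' @param exclusions optional exclusion tibble from [read_exclusion_regions()].
#' @param allowed_chroms chromosome names kept (compared without `chr` prefix).
#' @param upstream upstream window in bp ahead of the annotated TSS
#'   (default 1000, covering promoters).
#' @return The filtered [study_dataset()].
#' @export
apply_variant_filters <- function(ds, genes, exclusions = NULL,
                                  allowed_chroms = as.character(1:22),
                                  upstream = 1000L) {
  x <- ds$counts
  n0 <- nrow(x)
  chrom <- .norm_chrom(x$chrom)
  keep_auto <- chrom %in% .norm_chrom(allowed_chroms)
  n_auto <- sum(keep_auto)

  win <- .gene_windows(genes, upstream)
  hits <- .overlap_hits(chrom, x$pos, win)
  keep_gene <- keep_auto & (seq_len(n0) %in% S4Vectors::queryHits(hits))
  n_gene <- sum(keep_gene)

  keep <- keep_gene
  if (!is.null(exclusions) && nrow(exclusions)) {
    excl <- tibble::tibble(
      chrom = .norm_chrom(exclusions$chrom),
      start = exclusions$start, end = exclusions$end
    )
    ehits <- .overlap_hits(chrom, x$pos, excl)
    keep <- keep & !(seq_len(n0) %in% S4Vectors::queryHits(ehits))
  }
  out <- ds
  out$counts <- x[keep, , drop = FALSE]
  attr(out, "filter_log") <- tibble::tibble(
    stage = c("input", "allowed_chrom", "gene_window", "not_excluded"),
    n_snps = c(n0, n_auto, n_gene, sum(keep))
  )
  out
}

#' Assign SNPs to genes
#'
#' A SNP overlapping `k` gene windows (gene body plus strand-aware upstream
#' window) is assigned to all `k` genes; genes with no SNPs appear with an
#' empty vector. Warns when the dataset and annotation share no chromosome
#' names.
#'
#' @inheritParams apply_variant_filters
#' @return Named list mapping `gene_id` to a character vector of SNP ids.
#' @export
map_snps_to_genes <- function(ds, genes, upstream = 1000L) {
  x <- ds$counts
  chrom <- .norm_chrom(x$chrom)
  gchrom <- .norm_chrom(genes$chrom)
  if (nrow(x) && nrow(genes) && !length(intersect(chrom, gchrom))) {
    warning(sprintf(
      "no shared chromosome names between dataset (%d SNPs) and annotation (%d genes)",
      nrow(x), nrow(genes)
    ))
  }
  win <- .gene_windows(genes, upstream)
  hits <- .overlap_hits(chrom, x$pos, win)
  mapping <- setNames(
    vector("list", nrow(genes)),
    genes$gene_id
  )
  for (i in seq_along(mapping)) mapping[[i]] <- character()
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  sp <- split(x$snp_id[q], genes$gene_id[s])
  mapping[names(sp)] <- sp
  mapping
}
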