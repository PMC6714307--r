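#' Read and write paired-site allele depths as TSV
#'
#' The TSV carries one site per row with columns `chrom`, `pos`, `ref`,
#' `alt`, `t_ref`, `t_alt`, `n_ref`, `n_alt` (and `site_id` when present).
#'
#' @param sites a [PairedSites-class] object.
#' @param path file path.
#' @return `writePairedSitesTsv()` returns the path invisibly;
#'   `readPairedSitesTsv()` returns a [PairedSites-class].
#' @export
writePairedSitesTsv <- function(sites, path) {
  stopifnot(is(sites, "PairedSites"))
  write_tsv(siteData(sites), path)
}

#' @rdname writePairedSitesTsv
#' @export
readPairedSitesTsv <- function(path) {
  PairedSites(read_tsv(path))
}

#' Write paired-site allele depths as a minimal VCF 4.2
#'
#' Two sample columns (default `TUMOR`, `NORMAL`) with GT:AD fields; AD is
#' `ref,alt`. Genotypes are left as `./.` -- only the allele depths carry
#' information for the somatic test.
#'
#' @param sites a [PairedSites-class].
#' @param path output path (plain text).
#' @param tumor_sample,normal_sample sample column names.
#' @return the path, invisibly.
#' @export
writePairedSitesVcf <- function(sites, path, tumor_sample = "TUMOR",
                                normal_sample = "NORMAL") {
  stopifnot(is(sites, "PairedSites"))
  d <- siteData(sites)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths for the ref and alt alleles\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", tumor_sample, normal_sample), collapse = "\t"))
  body <- paste(d$chrom, d$pos, d$site_id, d$ref, d$alt, ".", ".", ".",
                "GT:AD",
                paste0("./.:", d$t_ref, ",", d$t_alt),
                paste0("./.:", d$n_ref, ",", d$n_alt), sep = "\t")
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Read paired-site allele depths from a VCF with per-sample AD
#'
#' Parses a VCF (via the VariantAnnotation package) whose samples carry an
#' `AD` FORMAT field and extracts tumor/normal ref/alt depths for
#' biallelic SNVs.
#'
#' @param path VCF path.
#' @param tumor_sample,normal_sample names of the two sample columns.
#' @return a [PairedSites-class].
#' @export
readPairedSitesVcf <- function(path, tumor_sample = "TUMOR",
                               normal_sample = "NORMAL") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readPairedSitesVcf() requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  smp <- colnames(vcf)
  if (!all(c(tumor_sample, normal_sample) %in% smp))
    stop("samples not found in VCF: expected ", tumor_sample, " and ",
         normal_sample)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF lacks the AD FORMAT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  get2 <- function(s, i) {
    v <- ad[, s][[i]]
    if (length(v) < 2 || anyNA(v[1:2])) c(NA_integer_, NA_integer_)
    else v[1:2]
  }
  n <- nrow(vcf)
  tm <- t(vapply(seq_len(n), function(i) get2(tumor_sample, i),
                 integer(2)))
  nm <- t(vapply(seq_len(n), function(i) get2(normal_sample, i),
                 integer(2)))
  ids <- names(rr)
  df <- data.frame(
    site_id = if (is.null(ids)) NULL else ids,
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    t_ref = tm[, 1], t_alt = tm[, 2],
    n_ref = nm[, 1], n_alt = nm[, 2],
    stringsAsFactors = FALSE)
  keep <- stats::complete.cases(df) & nchar(df$ref) == 1 &
    nchar(df$alt) == 1
  PairedSites(df[keep, , drop = FALSE])
}

#' Read and write gene-set collections in GMT format
#'
#' Reading uses the fgsea GMT parser; the universe must be supplied (GMT
#' files carry no universe). Writing emits the standard
#' `name<TAB>description<TAB>gene...` lines.
#'
#' @param path GMT file path.
#' @param universe character vector of the gene universe (reading only).
#' @param collection a [GeneSetList-class] (writing only).
#' @return `readGMT()` a [GeneSetList-class]; `writeGMT()` the path,
#'   invisibly.
#' @export
readGMT <- function(path, universe) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("readGMT() requires the fgsea package")
  GeneSetList(fgsea::gmtPathways(path), universe = universe)
}

#' @rdname readGMT
#' @export
writeGMT <- function(collection, path) {
  stopifnot(is(collection, "GeneSetList"))
  sets <- geneSets(collection)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1)),
    con, sep = "\n")
  invisible(path)
}

#' Write an RNA count container as TSV files
#'
#' Emits three files under `prefix`: `<prefix>_counts.tsv` (gene column +
#' one column per sample), `<prefix>_gene_lengths.tsv` and
#' `<prefix>_samples.tsv` (sample, group, total_mapped).
#'
#' @param m an [RNACountSet-class].
#' @param prefix path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
writeCountsTsv <- function(m, prefix) {
  stopifnot(is(m, "RNACountSet"))
  k <- SummarizedExperiment::assay(m, "counts")
  p1 <- paste0(prefix, "_counts.tsv")
  p2 <- paste0(prefix, "_gene_lengths.tsv")
  p3 <- paste0(prefix, "_samples.tsv")
  write_tsv(data.frame(gene = rownames(k), k, check.names = FALSE), p1)
  write_tsv(data.frame(gene = rownames(k),
                       length = SummarizedExperiment::rowData(m)$gene_length),
            p2)
  cd <- SummarizedExperiment::colData(m)
  write_tsv(data.frame(sample = rownames(cd), group = cd$group,
                       total_mapped = cd$total_mapped), p3)
  invisible(c(p1, p2, p3))
}

#' Read an RNA count container from TSV files
#'
#' Counterpart of [writeCountsTsv()].
#'
#' @param prefix path prefix used at writing time.
#' @return an [RNACountSet-class].
#' @export
readCountsTsv <- function(prefix) {
  k <- read_tsv(paste0(prefix, "_counts.tsv"))
  len <- read_tsv(paste0(prefix, "_gene_lengths.tsv"))
  smp <- read_tsv(paste0(prefix, "_samples.tsv"))
  counts <- as.matrix(k[, -1, drop = FALSE])
  rownames(counts) <- k$gene
  RNACountSet(counts,
              gene_lengths = stats::setNames(len$length, len$gene),
              groups = smp$group[match(colnames(counts), smp$sample)],
              total_mapped = smp$total_mapped[match(colnames(counts),
                                                    smp$sample)])
}
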