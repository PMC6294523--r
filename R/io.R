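#' Write and read genotype dosages as TSV
#'
#' Rows are SNPs (`snp_id`, `pos`, then one dosage column per sample);
#' byte-deterministic given the input.
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly (writer); a [genotype_matrix()] (reader).
#' @export
write_dosage_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- data.table::data.table(snp_id = G$snp_ids, pos = G$positions)
  samples <- rownames(G$dosages)
  if (is.null(samples)) samples <- sprintf("sample%04d", seq_len(nrow(G$dosages)))
  d <- cbind(d, data.table::as.data.table(t(G$dosages)))
  data.table::setnames(d, c("snp_id", "pos", samples))
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  dos <- t(as.matrix(d[, -(1:2)]))
  rownames(dos) <- colnames(d)[-(1:2)]
  genotype_matrix(dos, d$pos, d$snp_id)
}

#' Write and read an expression matrix as TSV
#'
#' Rows are genes (`gene_id` then one column per sample, header row of sample
#' ids).
#'
#' @param E an [expression_matrix()].
#' @param path file path.
#' @return `path` invisibly (writer); an [expression_matrix()] (reader).
#' @export
write_expression_tsv <- function(E, path) {
  stopifnot(inherits(E, "expression_matrix"))
  d <- data.table::data.table(gene_id = E$gene_ids)
  d <- cbind(d, data.table::as.data.table(signif(E$values, 6)))
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  vals <- as.matrix(d[, -1])
  expression_matrix(vals, d$gene_id)
}

#' Write and read gene annotation / truth tables as TSV
#'
#' Gene annotation columns: `gene_id`, `chrom`, `tss`. Truth columns:
#' `gene_id`, `snp_id`, `beta`, `coding_mode`; null genes are rows with an
#' empty `snp_id` and `beta` 0.
#'
#' @param genes,truth objects to write.
#' @param path file path.
#' @return `path` invisibly (writers); a data.frame / [truth_assignments()]
#'   (readers).
#' @export
write_gene_annotation_tsv <- function(genes, path) {
  data.table::fwrite(genes, path, sep = "\t")
  invisible(path)
}

#' @rdname write_gene_annotation_tsv
#' @export
read_gene_annotation_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname write_gene_annotation_tsv
#' @export
write_truth_tsv <- function(truth, path) {
  stopifnot(inherits(truth, "truth_assignments"))
  ent <- truth$entries[, c("gene_id", "snp_id", "beta", "coding_mode")]
  ent$beta <- signif(ent$beta, 6)
  nulls <- data.frame(gene_id = truth$null_gene_ids, snp_id = "",
                      beta = 0, coding_mode = "", stringsAsFactors = FALSE)
  data.table::fwrite(rbind(ent, nulls), path, sep = "\t")
  invisible(path)
}

#' @rdname write_gene_annotation_tsv
#' @export
read_truth_tsv <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t"))
  truth_assignments(d[d$snp_id != "", ], d$gene_id[d$snp_id == ""])
}

#' Write an association table as TSV
#'
#' Stable column order; floats at 6 significant digits.
#'
#' @param assoc an `association_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_association_tsv <- function(assoc, path) {
  d <- as.data.frame(assoc)
  for (col in c("beta", "se", "t_stat", "p_nominal"))
    d[[col]] <- signif(d[[col]], 6)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' Write genotypes as a minimal VCF 4.2
#'
#' One chromosome, biallelic sites with GT-only FORMAT; unphased genotypes
#' `0/0`, `0/1`, `1/1` encode the dosage of the coded (ALT) allele. REF/ALT
#' are placeholder alleles `A`/`B`-free nucleotides (`A`/`G`).
#'
#' @param G a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  samples <- rownames(G$dosages)
  if (is.null(samples)) samples <- sprintf("sample%04d", seq_len(nrow(G$dosages)))
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", G$chrom,
            max(G$positions, 1L)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  body <- vapply(seq_along(G$snp_ids), function(j) {
    paste(c(G$chrom, G$positions[j], G$snp_ids[j], "A", "G", ".", "PASS",
            ".", "GT", gt[G$dosages[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read dosages from a minimal VCF
#'
#' Expects a single-chromosome, biallelic VCF with GT genotypes. Dosage is
#' the ALT-allele count. Missing genotypes are an error by default
#' (`missing = "error"`) or mean-imputed and rounded (`missing = "impute"`)
#' for external data.
#'
#' @param path VCF path (plain or gzipped).
#' @param missing `"error"` or `"impute"`.
#' @return a [genotype_matrix()].
#' @export
read_vcf_dosages <- function(path, missing = c("error", "impute")) {
  missing <- match.arg(missing)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-variant VCF
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multiallelic records are not supported")
  if (length(unique(fix[, "CHROM"])) > 1)
    stop("expected a single-chromosome VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (!length(al) || anyNA(al) || any(al == ".")) NA_real_
      else sum(al != "0")
    }, numeric(1))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
  if (anyNA(dos)) {
    if (missing == "error") stop("missing genotypes in VCF (set missing='impute')")
    for (j in seq_len(nrow(dos))) {
      na <- is.na(dos[j, ])
      if (any(na)) dos[j, na] <- round(mean(dos[j, !na]))
    }
  }
  genotype_matrix(t(dos), as.integer(fix[, "POS"]), fix[, "ID"],
                  chrom = fix[1, "CHROM"])
}

#' Read a scenario configuration from YAML or JSON
#'
#' Recognised fields mirror [scenario_config()] arguments; `effects` may be
#' given as a nested map (`family`, `shape`, `scale`, `beta`).
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("config must be a mapping of scenario_config fields")
  if (!is.null(cfg$effects)) cfg$effects <- do.call(effect_dist, cfg$effects)
  known <- names(formals(scenario_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  do.call(scenario_config, cfg)
}

#' Write a run manifest
#'
#' JSON record of a pipeline invocation: package version, seed, configuration
#' snapshot and the inventory of output files with md5 checksums.
#'
#' @param path manifest path (`.json`).
#' @param config the [scenario_config()] used (serialised without function
#'   objects).
#' @param files character vector of produced files.
#' @param extra optional named list merged into the manifest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config, files, extra = list()) {
  cfg <- config
  class(cfg) <- NULL
  cfg$profile <- unclass(cfg$profile)
  cfg$spectrum <- unclass(cfg$spectrum)
  cfg$effects <- unclass(cfg$effects)
  man <- c(list(
    package = "eqtlpower",
    version = as.character(utils::packageVersion("eqtlpower")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    files = data.frame(path = files,
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(man)
}
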