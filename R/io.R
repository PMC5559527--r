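# Format boundaries. Internal coordinates are 1-based inclusive everywhere;
# BED input is converted on read. Variant tables travel either as VCF 4.2
# (per-sample AD and DP FORMAT fields; read back through vcfR) or as a plain
# TSV dialect with the same columns as the internal long table.

#' Write a long variant table as VCF 4.2
#'
#' One VCF row per mutation with `GT:AD:DP` per sample; `AD` is
#' `ref_reads,alt_reads`. Contig headers cover the 22 autosomes of the
#' simulated genome.
#'
#' @param variants Long table with `sample, chrom, pos, ref, alt_allele,
#'   alt_reads, depth, mutation_id`.
#' @param path Output path.
#' @param genome Genome label written to the header.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, genome = "GRCh37") {
  samples <- unique(variants$sample)
  muts <- unique(variants$mutation_id)
  idx <- variants[match(muts, variants$mutation_id), ]
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##reference=", genome),
    sprintf("##contig=<ID=%d,length=%d>", seq_along(.chrom_lengths),
            as.integer(.chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_along(muts), function(i) {
    m <- muts[i]
    cells <- vapply(samples, function(s) {
      row <- variants[variants$mutation_id == m & variants$sample == s, ]
      if (nrow(row) == 0L) return("./.:.,.:.")
      sprintf("0/1:%d,%d:%d", row$depth[1] - row$alt_reads[1],
              row$alt_reads[1], row$depth[1])
    }, character(1))
    paste(c(idx$chrom[i], idx$pos[i], m, idx$ref[i], idx$alt_allele[i],
            ".", "PASS", ".", "GT:AD:DP", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample VCF with AD/DP into the long variant table
#'
#' Parsed with `vcfR`; per-sample alt reads come from the second `AD` field
#' and depth from `DP` (falling back to the AD sum when DP is absent).
#'
#' @param path VCF path.
#' @param patient Patient id attached to every row.
#' @return Long data frame `patient, sample, mutation_id, chrom, pos, ref,
#'   alt_allele, alt_reads, depth`.
#' @export
read_variants_vcf <- function(path, patient = "patient1") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  samples <- colnames(ad)
  alt_mat <- apply(ad, 2L, function(col) {
    as.integer(vapply(strsplit(col, ","), function(x) {
      if (length(x) < 2L || x[2] == ".") NA_character_ else x[2]
    }, character(1)))
  })
  ref_mat <- apply(ad, 2L, function(col) {
    as.integer(vapply(strsplit(col, ","), function(x) {
      if (length(x) < 1L || x[1] == ".") NA_character_ else x[1]
    }, character(1)))
  })
  mutation_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste(fix$CHROM, fix$POS, fix$ALT, sep = ":"), fix$ID)
  out <- do.call(rbind, lapply(seq_along(samples), function(j) {
    depth <- dp[, j]
    miss <- is.na(depth)
    depth[miss] <- ref_mat[miss, j] + alt_mat[miss, j]
    data.frame(patient = patient, sample = samples[j],
               mutation_id = mutation_id,
               chrom = fix$CHROM, pos = as.numeric(fix$POS),
               ref = fix$REF, alt_allele = fix$ALT,
               alt_reads = alt_mat[, j], depth = as.numeric(depth),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read SEG copy-number profiles
#'
#' Tab-delimited with columns `sample, chrom, start, end, total_cn, minor_cn,
#' clonal_fraction` (1-based inclusive); an optional `#genome=` comment line
#' declares the build and round-trips as the `genome` attribute.
#'
#' @param seg SEG data frame.
#' @param path File path.
#' @param genome Optional genome build label.
#' @return `path` invisibly (writer); SEG data frame with `genome` attribute
#'   (reader).
#' @export
write_seg <- function(seg, path, genome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(genome)) writeLines(paste0("#genome=", genome), con)
  utils::write.table(seg, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  first <- readLines(path, n = 1L)
  genome <- NULL
  skip <- 0L
  if (startsWith(first, "#genome=")) {
    genome <- sub("^#genome=", "", first)
    skip <- 1L
  }
  seg <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                           stringsAsFactors = FALSE)
  attr(seg, "genome") <- genome
  seg
}

#' Read a BED file of regions
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention on read. A fourth column, when present,
#' becomes `gene`.
#'
#' @param path BED path.
#' @return Data frame `chrom, start, end` (+ `gene`).
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = bed[[1L]], start = bed[[2L]] + 1L, end = bed[[3L]],
                    stringsAsFactors = FALSE)
  if (ncol(bed) >= 4L) out$gene <- bed[[4L]]
  out
}

#' Write a simulated patient's pipeline inputs to a directory
#'
#' Emits `variants.vcf`, one `<sample>.seg` per specimen, `contexts.csv`,
#' `expression.csv`, `gep70_genes.csv`, `imaging.csv`, `clinical.csv` and a
#' `truth.json` with the full simulated ground truth. Everything round-trips
#' losslessly through the package readers ([read_patient_inputs()]).
#'
#' @param sim A `sim_patient` from [simulate_patient()].
#' @param out_dir Output directory (created if needed).
#' @param genome Genome label for the VCF/SEG headers.
#' @return Named list of written paths, invisibly.
#' @export
write_patient_inputs <- function(sim, out_dir, genome = "GRCh37") {
  stopifnot(inherits(sim, "sim_patient"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  paths <- list()
  paths$vcf <- file.path(out_dir, "variants.vcf")
  write_variants_vcf(sim$variants, paths$vcf, genome = genome)
  paths$seg <- vapply(unique(sim$segs$sample), function(s) {
    p <- file.path(out_dir, paste0(s, ".seg"))
    write_seg(sim$segs[sim$segs$sample == s, , drop = FALSE], p, genome = genome)
    p
  }, character(1))
  paths$contexts <- file.path(out_dir, "contexts.csv")
  write.csv(sim$contexts, paths$contexts, row.names = FALSE)
  paths$expression <- file.path(out_dir, "expression.csv")
  write.csv(data.frame(gene = rownames(sim$expression), sim$expression,
                       check.names = FALSE),
            paths$expression, row.names = FALSE)
  paths$gep70_genes <- file.path(out_dir, "gep70_genes.csv")
  write.csv(data.frame(gene = c(sim$gep70$up_genes, sim$gep70$down_genes),
                       set = c(rep("up", length(sim$gep70$up_genes)),
                               rep("down", length(sim$gep70$down_genes)))),
            paths$gep70_genes, row.names = FALSE)
  paths$imaging <- file.path(out_dir, "imaging.csv")
  write.csv(sim$imaging, paths$imaging, row.names = FALSE)
  paths$clinical <- file.path(out_dir, "clinical.csv")
  write.csv(sim$clinical, paths$clinical, row.names = FALSE)
  paths$truth <- file.path(out_dir, "truth.json")
  truth <- sim$truth
  truth$site_compositions <- as.data.frame(truth$site_compositions)
  truth$ccf_true <- as.data.frame(truth$ccf_true)
  truth$expected_vaf <- as.data.frame(truth$expected_vaf)
  jsonlite::write_json(truth, paths$truth, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a patient input directory written by [write_patient_inputs()]
#'
#' @param dir Directory path.
#' @param patient Patient id for the variant rows (defaults to the id stored
#'   in `imaging.csv`).
#' @return List `variants, contexts, segs, expression, gep70, imaging,
#'   clinical, truth` mirroring the `sim_patient` fields.
#' @export
read_patient_inputs <- function(dir, patient = NULL) {
  imaging <- read.csv(file.path(dir, "imaging.csv"), stringsAsFactors = FALSE)
  if (is.null(patient)) patient <- imaging$patient_id[1L]
  variants <- read_variants_vcf(file.path(dir, "variants.vcf"),
                                patient = patient)
  contexts <- read.csv(file.path(dir, "contexts.csv"), stringsAsFactors = FALSE)
  segs <- do.call(rbind, lapply(contexts$sample, function(s) {
    read_seg(file.path(dir, paste0(s, ".seg")))
  }))
  expr_df <- read.csv(file.path(dir, "expression.csv"), check.names = FALSE,
                      stringsAsFactors = FALSE)
  expression <- as.matrix(expr_df[, -1L, drop = FALSE])
  rownames(expression) <- expr_df$gene
  gs <- read.csv(file.path(dir, "gep70_genes.csv"), stringsAsFactors = FALSE)
  gep70 <- suppressWarnings(gep70_config(gs$gene[gs$set == "up"],
                                         gs$gene[gs$set == "down"]))
  clinical_path <- file.path(dir, "clinical.csv")
  clinical <- if (file.exists(clinical_path)) {
    read.csv(clinical_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  list(variants = variants, contexts = contexts, segs = segs,
       expression = expression, gep70 = gep70, imaging = imaging,
       clinical = clinical, truth = truth, patient_id = patient)
}
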