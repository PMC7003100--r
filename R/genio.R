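#' Marker panel container
#'
#' Validating constructor for the genotype container used throughout the
#' package: an n x m dosage matrix coded 0/1/2 (NA = missing call), a
#' genetic map, and a family label per individual. Per-marker frequencies
#' of the counted allele are computed on the observed calls.
#'
#' @param genotypes Numeric matrix, individuals in rows (rownames = ids),
#'   markers in columns (colnames = marker ids), codes in {0, 1, 2, NA}.
#' @param map data.frame with columns `marker`, `chrom` and `cM` and/or
#'   `pos_bp`, sorted by (chrom, position), one row per genotype column.
#' @param family Character/factor of family ids, one per individual
#'   (NA allowed, e.g. for founders or checks).
#' @return A list of class `marker_panel` with elements `genotypes`,
#'   `map`, `family`, `allele_freq`.
#' @export
marker_panel <- function(genotypes, map, family = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- sprintf("ind%04d", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes))) colnames(genotypes) <- map$marker
  if (!identical(ncol(genotypes), nrow(map)))
    stop("dimension mismatch: ", ncol(genotypes), " genotype columns vs ",
         nrow(map), " map rows")
  if (!all(colnames(genotypes) == map$marker))
    stop("genotype column names do not match map marker ids")
  dup <- map$marker[duplicated(map$marker)]
  if (length(dup))
    stop("duplicated marker id(s): ", paste(unique(dup), collapse = ", "))
  pos <- if ("cM" %in% names(map)) map$cM else map$pos_bp
  if (is.null(pos)) stop("map must carry a 'cM' and/or 'pos_bp' column")
  if (any(pos < 0)) stop("map positions must be nonnegative")
  unsrt <- unlist(tapply(pos, map$chrom, function(x) any(diff(x) < 0)))
  if (any(unsrt))
    stop("map not sorted: positions must be nondecreasing within chromosome")
  bad <- !(genotypes %in% c(0, 1, 2) | is.na(genotypes))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA; found ",
         paste(unique(genotypes[bad])[1:min(3, sum(bad))], collapse = ", "))
  if (is.null(family)) family <- rep(NA_character_, nrow(genotypes))
  if (length(family) != nrow(genotypes))
    stop("family must have one entry per individual")
  structure(list(
    genotypes = genotypes,
    map = map,
    family = as.character(family),
    allele_freq = colMeans(genotypes, na.rm = TRUE) / 2
  ), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  nmiss <- sum(is.na(x$genotypes))
  cat("marker_panel:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "markers on", length(unique(x$map$chrom)),
      "chromosome(s)\n")
  cat("  families:", length(unique(stats::na.omit(x$family))),
      " missing calls:", sprintf("%.2f%%", 100 * nmiss / length(x$genotypes)), "\n")
  invisible(x)
}

#' @export
dim.marker_panel <- function(x) dim(x$genotypes)

#' Subset a marker panel
#'
#' @param panel A [marker_panel()].
#' @param individuals,markers Row/column selectors (names, indices or
#'   logical vectors); `NULL` keeps everything.
#' @return A [marker_panel()].
#' @export
subset_panel <- function(panel, individuals = NULL, markers = NULL) {
  g <- panel$genotypes
  fam <- panel$family
  map <- panel$map
  if (!is.null(individuals)) {
    idx <- if (is.character(individuals)) match(individuals, rownames(g)) else individuals
    if (is.numeric(idx) && anyNA(idx)) stop("unknown individual id(s)")
    g <- g[idx, , drop = FALSE]
    fam <- fam[idx]
  }
  if (!is.null(markers)) {
    jdx <- if (is.character(markers)) match(markers, colnames(g)) else markers
    if (is.numeric(jdx) && anyNA(jdx)) stop("unknown marker id(s)")
    g <- g[, jdx, drop = FALSE]
    map <- map[jdx, , drop = FALSE]
  }
  marker_panel(g, map, fam)
}

#' Write a marker panel to plain-text files
#'
#' Genotypes go to a tab-separated matrix (rows = individuals, first
#' column `id`, remaining header = marker ids), the map to a TSV with
#' columns (marker, chrom, cM) plus `pos_bp` when available, and family
#' labels to a two-column TSV.
#'
#' @param panel A [marker_panel()].
#' @param geno_path,map_path,fam_path Output file paths.
#' @export
write_panel <- function(panel, geno_path, map_path, fam_path) {
  g <- data.frame(id = rownames(panel$genotypes), panel$genotypes,
                  check.names = FALSE)
  utils::write.table(g, geno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  keep <- intersect(c("marker", "chrom", "cM", "pos_bp"), names(panel$map))
  utils::write.table(panel$map[, keep], map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(id = rownames(panel$genotypes), family = panel$family),
    fam_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(panel)
}

#' Read a marker panel from plain-text files
#'
#' Inverse of [write_panel()]. Validation (unique ids, sorted map,
#' dimension agreement) happens in the [marker_panel()] constructor.
#'
#' @param geno_path TSV genotype matrix (first column `id`).
#' @param map_path TSV map (marker, chrom, cM and/or pos_bp).
#' @param fam_path Optional TSV with columns id, family.
#' @return A [marker_panel()].
#' @export
read_panel <- function(geno_path, map_path, fam_path = NULL) {
  g <- utils::read.table(geno_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(g$id)
  if (anyDuplicated(ids))
    stop("duplicated individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  geno <- as.matrix(g[, setdiff(names(g), "id"), drop = FALSE])
  storage.mode(geno) <- "double"
  rownames(geno) <- ids
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  fam <- NULL
  if (!is.null(fam_path)) {
    ft <- utils::read.table(fam_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    fam <- ft$family[match(ids, ft$id)]
  }
  marker_panel(geno, map, fam)
}

#' Read a minimal VCF into a marker panel
#'
#' Parses only the GT field of an uncompressed or bgzipped VCF:
#' 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> missing (phased separators
#' accepted). Rows become markers named `Gm<CHROM>_<POS>` unless the VCF
#' ID column is set.
#'
#' @param vcf_path Path to the VCF.
#' @param fam_path Optional family TSV as in [read_panel()].
#' @return A [marker_panel()].
#' @export
read_vcf_panel <- function(vcf_path, fam_path = NULL) {
  con <- if (grepl("\\.(gz|bgz)$", vcf_path)) gzfile(vcf_path) else file(vcf_path)
  lines <- readLines(con)
  close(con)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) stop("not a VCF: missing #CHROM header line")
  cols <- strsplit(sub("^#", "", hdr[1]), "\t")[[1]]
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("VCF contains no variant records")
  rec <- do.call(rbind, strsplit(body, "\t"))
  colnames(rec) <- cols
  samples <- cols[-(1:9)]
  gt <- sub(":.*", "", rec[, samples, drop = FALSE])
  code <- matrix(NA_real_, nrow(gt), ncol(gt))
  code[gt %in% c("0/0", "0|0")] <- 0
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  code[gt %in% c("1/1", "1|1")] <- 2
  ids <- rec[, "ID"]
  noid <- ids == "." | ids == ""
  ids[noid] <- sprintf("Gm%s_%s", rec[noid, "CHROM"], rec[noid, "POS"])
  geno <- t(code)
  rownames(geno) <- samples
  colnames(geno) <- ids
  map <- data.frame(marker = ids,
                    chrom = rec[, "CHROM"],
                    pos_bp = as.integer(rec[, "POS"]),
                    stringsAsFactors = FALSE)
  fam <- NULL
  if (!is.null(fam_path)) {
    ft <- utils::read.table(fam_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    fam <- ft$family[match(samples, ft$id)]
  }
  marker_panel(geno, map, fam)
}

# Modal observed code of a vector; ties broken toward the smaller code so
# the rule is deterministic. Returns NA when nothing is observed.
.mode_code <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  tb <- table(x)
  as.numeric(names(tb)[which.max(tb)])
}

#' Impute missing calls and filter on minor allele frequency
#'
#' Missing calls are replaced by the within-family modal code (falling
#' back to the global mode when a family has no observed call for the
#' marker, and for individuals without a family label). Markers whose
#' minor allele frequency, computed after imputation, falls below
#' `maf_min` are removed. Observed calls are never altered and the filter
#' is idempotent.
#'
#' @param panel A [marker_panel()].
#' @param maf_min MAF threshold in [0, 0.5].
#' @return The imputed/filtered [marker_panel()], with an attribute `qc`
#'   (list: n_imputed, n_removed, n_retained, removed ids).
#' @export
impute_and_filter <- function(panel, maf_min = 0.05) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must lie in [0, 0.5]")
  geno <- panel$genotypes
  n_imputed <- 0L
  if (anyNA(geno)) {
    fam <- panel$family
    fam[is.na(fam)] <- ".nofam"
    gmode <- apply(geno, 2, .mode_code)
    for (f in unique(fam)) {
      rows <- which(fam == f)
      sub <- geno[rows, , drop = FALSE]
      miss_cols <- which(colSums(is.na(sub)) > 0)
      for (j in miss_cols) {
        mj <- .mode_code(sub[, j])
        if (is.na(mj)) mj <- gmode[j]
        hole <- is.na(sub[, j])
        geno[rows[hole], j] <- mj
        n_imputed <- n_imputed + sum(hole)
      }
    }
    if (anyNA(geno)) {
      # markers missing in every individual: nothing to anchor on
      allmiss <- colSums(!is.na(geno)) == 0
      geno <- geno[, !allmiss, drop = FALSE]
      panel$map <- panel$map[!allmiss, , drop = FALSE]
    }
  }
  p <- colMeans(geno) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min
  if (!any(keep))
    stop("no polymorphic markers remain after MAF filter at ", maf_min)
  out <- marker_panel(geno[, keep, drop = FALSE],
                      panel$map[keep, , drop = FALSE], panel$family)
  attr(out, "qc") <- list(n_imputed = n_imputed,
                          n_removed = sum(!keep),
                          n_retained = sum(keep),
                          removed = colnames(geno)[!keep])
  out
}
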