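# File formats: contour CSV (contour_id, point_index, x_um, y_um
# [, orientation]), SAM measures CSV (line_id, replicate, height_um,
# radius_um), estimator CSV with publication column names, and the R/qtl-style
# "csv" cross dialect (header rows: names / chromosomes / cM positions;
# genotypes A/H/B, "-" missing).

#' Read and write SAM contour files
#'
#' The contour CSV dialect has columns `contour_id`, `point_index`, `x_um`,
#' `y_um` and optionally `orientation`. Coordinates are y-up micrometres; if
#' the file carries a `coordinate_system` column equal to `"pixel"` (y-down),
#' the y axis is flipped at read time. `point_index` must increase within
#' each contour.
#'
#' @param path File path.
#' @param contours A contour tibble (`contour_id`, `point_index`, `x`, `y`
#'   and optionally `orientation`).
#' @return `read_contours()` returns a contour tibble (possibly empty, with a
#'   warning for an empty file); `write_contours()` returns `path`
#'   invisibly. A write-then-read round trip is exact to full double
#'   precision.
#' @export
read_contours <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) {
    warn("contour file is empty.")
    return(tibble(contour_id = character(), point_index = integer(),
                  x = numeric(), y = numeric()))
  }
  need <- c("contour_id", "point_index", "x_um", "y_um")
  if (!all(need %in% names(d))) {
    abort(sprintf("malformed contour file %s: need columns %s.",
                  path, paste(need, collapse = ", ")))
  }
  bad <- which(!is.finite(d$x_um) | !is.finite(d$y_um))
  if (length(bad)) {
    abort(sprintf("malformed row %d in %s: non-numeric coordinates.",
                  bad[1] + 1L, path))
  }
  for (id in unique(d$contour_id)) {
    pi <- d$point_index[d$contour_id == id]
    if (any(diff(pi) <= 0)) {
      abort(sprintf("contour `%s`: point_index is not strictly increasing.", id))
    }
  }
  out <- tibble(contour_id = as.character(d$contour_id),
                point_index = as.integer(d$point_index),
                x = d$x_um, y = d$y_um)
  if ("coordinate_system" %in% names(d) && any(d$coordinate_system == "pixel")) {
    flip <- d$coordinate_system == "pixel"
    out$y[flip] <- -out$y[flip]
  }
  if ("orientation" %in% names(d)) out$orientation <- d$orientation
  out
}

#' @rdname read_contours
#' @export
write_contours <- function(contours, path) {
  stopifnot(is.data.frame(contours))
  d <- data.frame(contour_id = contours$contour_id,
                  point_index = contours$point_index,
                  x_um = contours$x, y_um = contours$y)
  if ("orientation" %in% names(contours)) d$orientation <- contours$orientation
  utils::write.csv(format_full(d), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision decimal formatting so numeric round trips are exact
format_full <- function(d) {
  for (j in seq_along(d)) {
    if (is.double(d[[j]])) d[[j]] <- sprintf("%.17g", d[[j]])
  }
  d
}

#' Read and write SAM primary-measure tables
#'
#' CSV with columns `line_id`, `replicate`, `height_um`, `radius_um`;
#' returned with plain `height`/`radius` names (micrometres are the package's
#' working unit).
#'
#' @param path File path.
#' @param measures Tibble with `line_id`, `replicate`, `height`, `radius`.
#' @export
read_sam_measures <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "replicate", "height_um", "radius_um")
  if (!all(need %in% names(d))) {
    abort(sprintf("measures file needs columns %s.", paste(need, collapse = ", ")))
  }
  tibble(line_id = as.character(d$line_id), replicate = d$replicate,
         height = d$height_um, radius = d$radius_um)
}

#' @rdname read_sam_measures
#' @export
write_sam_measures <- function(measures, path) {
  d <- data.frame(line_id = measures$line_id, replicate = measures$replicate,
                  height_um = measures$height, radius_um = measures$radius)
  utils::write.csv(format_full(d), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a parabolic-estimator table with publication column names
#'
#' Writes one row per observation with the eight estimator columns renamed to
#' the conventional table headings: Height, Radius, H/R, Vol., Surf. Area,
#' Arc Len., Para. Coeff., Area.
#'
#' @param estimators Output of [sam_estimators()].
#' @param path File path.
#' @export
write_estimators <- function(estimators, path) {
  d <- as.data.frame(estimators)
  internal <- names(estimator_display_names)
  keep <- c(intersect(c("line_id", "replicate"), names(d)), internal)
  d <- d[keep]
  names(d)[match(internal, names(d))] <- unname(estimator_display_names)
  utils::write.csv(format_full(d), path, row.names = FALSE)
  invisible(path)
}

#' Read and write crosses in the R/qtl-style "csv" dialect
#'
#' Row 1 holds phenotype names followed by marker names; row 2 leaves
#' phenotype cells blank and gives each marker's chromosome; row 3 likewise
#' gives cM positions; each following row is one individual, phenotype values
#' then genotype letters (`A` = recurrent-parent homozygote, `H` =
#' heterozygote, `B` = donor homozygote, `-` = missing).
#'
#' @param path File path.
#' @param cross A `sam_cross` object.
#' @return `read_cross()` returns a `sam_cross`; a write/read round trip
#'   reproduces the genotype matrix exactly.
#' @export
read_cross <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) < 4) abort("cross file needs 3 header rows and >= 1 individual.")
  header <- as.character(raw[1, ])
  chr_row <- as.character(raw[2, ])
  pos_row <- as.character(raw[3, ])
  is_pheno <- chr_row == "" | is.na(chr_row)
  if (!any(is_pheno)) abort("no phenotype columns found (blank chromosome cells).")
  if (!any(!is_pheno)) abort("no marker columns found.")
  n_ph <- max(which(is_pheno))
  if (any(!is_pheno[seq_len(n_ph)])) {
    abort("phenotype columns must precede marker columns.")
  }
  markers <- header[!is_pheno]
  chrs <- chr_row[!is_pheno]
  pos <- suppressWarnings(as.numeric(pos_row[!is_pheno]))
  if (any(is.na(pos))) abort("marker count mismatch between header rows (bad cM positions).")
  body <- raw[-(1:3), , drop = FALSE]
  glet <- as.matrix(body[, !is_pheno, drop = FALSE])
  bad <- matrix(!glet %in% c("A", "H", "B", "-"), nrow(glet))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("unknown genotype letter `%s` at individual %d, marker `%s`.",
                  glet[i[1], i[2]], i[1], markers[i[2]]))
  }
  geno <- matrix(match(glet, c("A", "H", "B")) - 1L, nrow(glet), ncol(glet))
  pheno <- as.data.frame(body[, is_pheno, drop = FALSE])
  names(pheno) <- header[is_pheno]
  for (nm in setdiff(names(pheno), "line_id")) {
    pheno[[nm]] <- suppressWarnings(as.numeric(pheno[[nm]]))
  }
  if (!"line_id" %in% names(pheno)) {
    pheno$line_id <- sprintf("ind_%03d", seq_len(nrow(pheno)))
  }
  # preserve map order as given (chromosome blocks in file order)
  map <- tibble(marker = markers, chr = type_convert_chr(chrs), pos = pos)
  sam_cross(map, geno, as_tibble(pheno))
}

type_convert_chr <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (any(is.na(num))) x else num
}

#' @rdname read_cross
#' @export
write_cross <- function(cross, path) {
  stopifnot(inherits(cross, "sam_cross"))
  ph <- as.data.frame(cross$pheno)
  ph <- ph[c("line_id", setdiff(names(ph), "line_id"))]
  glet <- matrix(c("A", "H", "B")[cross$geno + 1L],
                 nrow(cross$geno), ncol(cross$geno))
  glet[is.na(glet)] <- "-"
  header <- c(names(ph), cross$map$marker)
  row2 <- c(rep("", ncol(ph)), as.character(cross$map$chr))
  row3 <- c(rep("", ncol(ph)), sprintf("%.17g", cross$map$pos))
  ph_chr <- as.data.frame(format_full(ph))
  body <- cbind(as.matrix(ph_chr), glet)
  lines <- c(paste(header, collapse = ","),
             paste(row2, collapse = ","),
             paste(row3, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a scan result as TSV
#'
#' Columns `chr`, `pos_cM`, `marker`, `lod`.
#' @param scan A `sam_scan` object.
#' @param path File path.
#' @export
write_scan <- function(scan, path) {
  d <- data.frame(chr = scan$chr, pos_cM = scan$pos,
                  marker = ifelse(is.na(scan$marker), "", scan$marker),
                  lod = scan$lod)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
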