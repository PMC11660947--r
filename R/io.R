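#' @include stats.R
NULL

#' Read a gradient scheme from bvals/bvecs text files
#'
#' The widely used two-file dialect: `bvals` holds whitespace-separated
#' b-values on one line; `bvecs` holds three lines (x, y, z components),
#' one column per measurement.
#'
#' @param bvalFile,bvecFile paths.
#' @return a [GradientScheme-class].
#' @export
readGradientScheme <- function(bvalFile, bvecFile) {
  b <- scan(bvalFile, quiet = TRUE)
  v <- as.matrix(read.table(bvecFile))
  if (nrow(v) != 3L && ncol(v) == 3L) v <- t(v)
  if (nrow(v) != 3L) stop("bvecs must have three rows (x, y, z)")
  if (ncol(v) != length(b)) stop("bvals and bvecs disagree in length")
  g <- t(v)
  nrm <- sqrt(rowSums(g^2))
  renorm <- b > 0 & nrm > 0
  g[renorm, ] <- g[renorm, ] / nrm[renorm]
  gradientScheme(b, g)
}

#' Write a gradient scheme as bvals/bvecs text files
#'
#' @param scheme a [GradientScheme-class].
#' @param bvalFile,bvecFile output paths.
#' @export
writeGradientScheme <- function(scheme, bvalFile, bvecFile) {
  writeLines(paste(format(scheme@bValues, trim = TRUE), collapse = " "),
             bvalFile)
  v <- t(scheme@directions)
  writeLines(apply(v, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvecFile)
  invisible(NULL)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around RNifti for the volumes the pipeline exchanges
#' (DWI, tensor components, FA/MD, RGB and flag maps).
#'
#' @param path NIfTI file path.
#' @return `readVolume`: a numeric array with a `voxelSize` attribute (mm).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "voxelSize") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(out))))]
  out
}

#' @rdname readVolume
#' @param x numeric/logical array to write.
#' @param voxelSize numeric(3) voxel size in mm.
#' @export
writeVolume <- function(x, path, voxelSize = c(2, 2, 2)) {
  img <- RNifti::asNifti(x * 1)
  RNifti::pixdim(img) <- c(voxelSize, rep(1, max(0, length(dim(x)) - 3L)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read ROI specifications from a NIfTI label mask
#'
#' Integer labels follow the convention 1 = projection-left,
#' 2 = association-left, 3 = projection-right, 4 = association-right.
#'
#' @param mask path to a NIfTI label volume, or an integer array.
#' @return named list of [ROISpec-class] (entries `left`/`right`, each
#'   with `projection`/`association`), omitting absent labels.
#' @export
readRoiMask <- function(mask) {
  if (is.character(mask)) mask <- readVolume(mask)
  key <- list(c("projection", "left"), c("association", "left"),
              c("projection", "right"), c("association", "right"))
  out <- list()
  for (lab in 1:4) {
    idx <- which(mask == lab, arr.ind = TRUE)
    if (!nrow(idx)) next
    s <- key[[lab]]
    out[[s[2]]][[s[1]]] <- roiSpec(s[1], s[2], idx)
  }
  out
}

#' Read an ROI from JSON voxel coordinates
#'
#' The JSON object needs fields `site`, `hemisphere` and `voxels` (an
#' array of [x, y, z] triples, 0-based as is conventional on disk; they
#' are converted to this package's 1-based grid indices).
#'
#' @param path JSON file path.
#' @return an [ROISpec-class].
#' @export
readRoiJson <- function(path) {
  spec <- jsonlite::fromJSON(path)
  vox <- matrix(as.integer(as.matrix(spec$voxels)), ncol = 3) + 1L
  roiSpec(spec$site, spec$hemisphere, vox,
          mode = if (!is.null(spec$mode)) spec$mode else "conventional")
}

#' Write per-subject ALPS results as CSV
#'
#' Column layout: subject, hemisphere, mode, ALPS, Dxx_proj, Dyy_proj,
#' Dxx_assoc, Dzz_assoc, FA_proj, FA_assoc, MD_proj, MD_assoc,
#' excluded_voxels (plus group and clinicalScore when present).
#'
#' @param records data.frame as returned by [makeCohort()] or
#'   [analyzePhantom()] (a `subject` column is added if missing).
#' @param path output CSV path.
#' @export
writeAlpsTable <- function(records, path) {
  if (!"subject" %in% names(records)) records$subject <- "phantom"
  cols <- c(subject = "subject", group = "group", hemisphere = "hemisphere",
            mode = "mode", ALPS = "alps", Dxx_proj = "dxxProj",
            Dyy_proj = "dyyProj", Dxx_assoc = "dxxAssoc",
            Dzz_assoc = "dzzAssoc", FA_proj = "faProj", FA_assoc = "faAssoc",
            MD_proj = "mdProj", MD_assoc = "mdAssoc",
            excluded_voxels = "excludedVoxels",
            clinicalScore = "clinicalScore")
  cols <- cols[cols %in% names(records)]
  out <- records[, unname(cols), drop = FALSE]
  names(out) <- names(cols)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a flag map as NIfTI with a JSON sidecar
#'
#' @param flags a [FlagMap-class].
#' @param path output NIfTI path; the sidecar records the threshold at
#'   `<path minus extension>.json`.
#' @param voxelSize numeric(3) mm.
#' @export
writeFlagMap <- function(flags, path, voxelSize = c(2, 2, 2)) {
  writeVolume(flags@flags, path, voxelSize)
  side <- sub("\\.nii(\\.gz)?$", "", path)
  jsonlite::write_json(list(threshold = flags@threshold,
                            nFlagged = sum(flags@flags)),
                       paste0(side, ".json"), auto_unbox = TRUE)
  invisible(path)
}
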