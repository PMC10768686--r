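# Readers and writers: NIfTI volumes, FSL-style bvec/bval gradient
# tables, SH-field sidecar JSON, and model serialization.
#
# Processing is voxel-space only: gradient directions are not reoriented
# by the NIfTI affine (phantom outputs use identity affines; for real
# data the caller must supply bvecs in the volume's voxel frame).

B0_THRESHOLD <- 50 # s/mm^2: volumes with b below this are b=0

# plain numeric array from an RNifti image (drops the niftiImage class)
niftiArray <- function(img) {
  array(as.vector(img), dim(img))
}

#' Read a DWI volume with FSL-style gradient tables
#'
#' Loads a 4D NIfTI and its `bvec` (3 x N, unit columns for b > 0) and
#' `bval` (1 x N) text files.  Volumes are split into b=0 (b < 50) and a
#' single diffusion-weighted shell, with b=0 volumes moved first;
#' multi-shell input (more than one b > 50 cluster at 10% tolerance) is
#' rejected.
#'
#' @param niftiPath path to the 4D NIfTI.
#' @param bvecPath,bvalPath paths to the gradient table text files.
#' @param maskPath optional path to a binary mask NIfTI.
#' @return a [DWIVolume-class].
#' @export
readDwi <- function(niftiPath, bvecPath, bvalPath, maskPath = NULL) {
  arr <- niftiArray(RNifti::readNifti(niftiPath))
  if (length(dim(arr)) != 4L) stop("expected a 4D NIfTI volume")
  bvec <- as.matrix(utils::read.table(bvecPath))
  bval <- as.numeric(utils::read.table(bvalPath))
  if (nrow(bvec) != 3L)
    stop("bvec must have 3 rows (FSL convention)")
  if (ncol(bvec) != length(bval))
    stop("bvec and bval disagree on the number of volumes")
  if (dim(arr)[4L] != length(bval))
    stop(sprintf("NIfTI has %d volumes but the gradient table lists %d",
                 dim(arr)[4L], length(bval)))
  isB0 <- bval < B0_THRESHOLD
  bs <- bval[!isB0]
  if (!length(bs)) stop("no diffusion-weighted volumes (all b < 50)")
  if ((max(bs) - min(bs)) / mean(bs) > 0.1)
    stop(sprintf(
      "multi-shell input (b-values %s): extract a single shell first",
      paste(sort(unique(bval)), collapse = ", ")))
  D <- t(bvec[, !isB0, drop = FALSE])
  nrm <- sqrt(rowSums(D^2))
  if (any(abs(nrm - 1) > 0.01))
    stop("bvec columns for b > 0 must be unit vectors (tolerance 0.01)")
  D <- D / nrm
  ord <- c(which(isB0), which(!isB0)) # b0 volumes first
  scheme <- GradientScheme(D, mean(bs), sum(isB0))
  mask <- if (!is.null(maskPath)) {
    m <- niftiArray(RNifti::readNifti(maskPath))
    if (!identical(dim(m), dim(arr)[1:3])) stop("mask shape mismatch")
    array(m > 0, dim(m))
  } else NULL
  new("DWIVolume", data = arr[, , , ord, drop = FALSE], scheme = scheme,
      mask = mask)
}

#' Write a DWI volume with FSL-style gradient tables
#'
#' @param dwi a [DWIVolume-class].
#' @param niftiPath output NIfTI path (`.nii` or `.nii.gz`).
#' @param bvecPath,bvalPath output gradient table paths.
#' @param voxelSize voxel size (mm) recorded in the NIfTI header.
#' @return invisibly, `niftiPath`.
#' @export
writeDwi <- function(dwi, niftiPath, bvecPath, bvalPath,
                     voxelSize = c(2, 2, 2)) {
  stopifnot(is(dwi, "DWIVolume"))
  sch <- dwi@scheme
  img <- RNifti::asNifti(dwi@data, pixdim = c(voxelSize, 1))
  RNifti::writeNifti(img, niftiPath)
  bvec <- cbind(matrix(0, 3L, sch@nB0), t(sch@directions))
  bval <- c(rep(0, sch@nB0), rep(sch@bValue, nDirections(sch)))
  utils::write.table(format(bvec, digits = 10), bvecPath,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(t(bval), bvalPath, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(niftiPath)
}

#' Write a binary mask as NIfTI
#'
#' @param mask logical 3D array.
#' @param path output path.
#' @param voxelSize voxel size in mm.
#' @return invisibly, `path`.
#' @export
writeMask <- function(mask, path, voxelSize = c(2, 2, 2)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)),
                         pixdim = c(voxelSize, 1), datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write / read an SH coefficient field as NIfTI plus sidecar JSON
#'
#' The 4D NIfTI stores one volume per coefficient; the sidecar JSON
#' records the basis order, the convention label and the field kind
#' (`"signal"` or `"fodf"`).  Reading validates the sidecar and, when
#' `expectOrder` is given, the basis order.
#'
#' @param field an [SHField-class].
#' @param path NIfTI output path; the sidecar is written next to it with
#'   a `.json` extension.
#' @return invisibly, `path` (write) or the [SHField-class] (read).
#' @export
writeShField <- function(field, path) {
  stopifnot(is(field, "SHField"))
  img <- RNifti::asNifti(field@data, pixdim = c(field@voxelSize, 1))
  RNifti::writeNifti(img, path)
  meta <- list(maxOrder = field@basis@maxOrder,
               convention = field@basis@convention,
               kind = field@kind,
               voxelSize = field@voxelSize)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeShField
#' @param expectOrder optional required basis order.
#' @param expectKind optional required field kind.
#' @export
readShField <- function(path, expectOrder = NULL, expectKind = NULL) {
  sp <- sidecarPath(path)
  if (!file.exists(sp))
    stop("missing basis sidecar: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!is.null(expectOrder) && meta$maxOrder != expectOrder)
    stop(sprintf("field has SH order %d; order %d required",
                 meta$maxOrder, expectOrder))
  if (!is.null(expectKind) && meta$kind != expectKind)
    stop(sprintf("field kind is '%s'; '%s' required", meta$kind, expectKind))
  arr <- niftiArray(RNifti::readNifti(path))
  basis <- SHBasis(as.integer(meta$maxOrder), meta$convention)
  SHField(arr, basis, as.numeric(meta$voxelSize), kind = meta$kind)
}

#' Read a binary mask NIfTI
#'
#' @param path NIfTI path.
#' @return logical 3D array.
#' @export
readMask <- function(path) {
  m <- niftiArray(RNifti::readNifti(path))
  array(m > 0, dim(m))
}

#' Save / load a trained model as JSON
#'
#' Weights, batch-normalization statistics and the architecture /
#' training configuration are serialized to a single JSON file (text,
#' fully reproducible round trip at double precision).
#'
#' @param model a `dcsdModel`.
#' @param path output `.json` path.
#' @param meta optional named list of extra metadata (loss weights,
#'   seeds, training config) stored verbatim.
#' @return invisibly, `path` (save) or the `dcsdModel` (load).
#' @export
saveModel <- function(model, path, meta = list()) {
  ser <- list(
    arch = model$arch, nCoef = model$nCoef, seed = model$seed,
    hidden = model$hidden, widths = model$widths,
    shortcut = model$shortcut,
    params = lapply(model$params, function(p)
      list(dim = dim(p) %||% length(p), values = as.numeric(p))),
    bn = lapply(model$bn, function(s) list(mean = s$mean, var = s$var)),
    meta = meta
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(ser$params, function(p) {
    v <- as.numeric(p$values)
    if (length(p$dim) == 2L) matrix(v, p$dim[1], p$dim[2]) else v
  })
  bn <- lapply(ser$bn, function(s) {
    env <- bnStateInit(length(s$mean))
    env$mean <- as.numeric(s$mean)
    env$var <- as.numeric(s$var)
    env
  })
  model <- list(arch = ser$arch, nCoef = as.integer(ser$nCoef),
                seed = as.integer(ser$seed), params = params, bn = bn,
                meta = ser$meta)
  if (ser$arch == "patch_cnn") {
    model$hidden <- as.integer(ser$hidden)
    model$shortcut <- ser$shortcut
  } else {
    model$widths <- as.integer(ser$widths)
  }
  structure(model, class = "dcsdModel")
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path configuration file path (`.yaml`/`.yml` or `.json`).
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
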