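#' @useDynLib lungprm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

HU_MIN <- -1024
HU_MAX <- 3071

#' CT volume container
#'
#' A `ct_volume` holds a 3D scalar grid of attenuation values in Hounsfield
#' units (HU) together with its physical metadata.  Values are clamped to the
#' 12-bit CT range \[-1024, 3071\] HU on construction.
#'
#' @param voxels numeric 3D array of attenuation values (HU).
#' @param spacing numeric length-3, physical voxel size in mm (all > 0).
#' @param origin numeric length-3, physical coordinate of voxel (1,1,1) in mm.
#' @param phase one of `"inspiratory"`, `"expiratory"`,
#'   `"generated-expiratory"`.
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `origin`, `phase`.
#' @examples
#' v <- ct_volume(array(-1000, c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      phase = c("inspiratory", "expiratory",
                                "generated-expiratory")) {
  phase <- match.arg(phase)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("expected 3D volume")
  if (!is.numeric(voxels))
    stop("expected scalar (numeric) voxel data")
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("voxel values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  voxels[voxels < HU_MIN] <- HU_MIN
  voxels[voxels > HU_MAX] <- HU_MAX
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), phase = phase),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %dx%dx%d, spacing %s mm, phase %s, HU [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              x$phase, min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary lung mask
#'
#' @param voxels logical (or 0/1) 3D array; `TRUE` marks lung.
#' @param spacing voxel size in mm.
#' @return Object of class `lung_mask`.
#' @export
lung_mask <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("expected 3D mask")
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask must not contain NA")
  if (!any(voxels)) stop("mask is empty")
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "lung_mask")
}

PRM_LABELS <- c(background = 0L, normal = 1L, fSAD = 2L, emphysema = 3L)

#' PRM label map
#'
#' Voxel labels are 0 = background, 1 = normal parenchyma, 2 = fSAD
#' (functional small airway disease), 3 = emphysema.  Non-background labels
#' may occur only inside the lung mask that produced the map.
#'
#' @param labels integer 3D array over \{0, 1, 2, 3\}.
#' @param source provenance of the map: `"ground-truth"`, `"predicted"`,
#'   `"threshold-derived"` or `"fused"`.
#' @param spacing voxel size in mm.
#' @return Object of class `prm_map`.
#' @export
prm_map <- function(labels, source = c("ground-truth", "predicted",
                                       "threshold-derived", "fused"),
                    spacing = c(1, 1, 1)) {
  source <- match.arg(source)
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("expected 3D label grid")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L | labels > 3L))
    stop("labels must be integers in 0..3")
  structure(list(labels = labels, source = source,
                 spacing = as.numeric(spacing)),
            class = "prm_map")
}

#' Read a CT volume or label map from NIfTI
#'
#' Reads a scalar 3D NIfTI volume; attenuation values are clamped to
#' \[-1024, 3071\] HU.  Distinct errors are raised for a missing file,
#' non-3D data, and non-scalar voxel data.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param phase phase tag to attach to the returned volume.
#' @param clamp clamp values to the HU range (disable when reading label
#'   maps or masks).
#' @return A [ct_volume].
#' @export
read_volume <- function(path, phase = "inspiratory", clamp = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(img[, , , 1L], d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) stop("expected 3D volume, got ", length(d), "D data")
  if (!is.numeric(img)) stop("expected scalar (numeric) voxel data")
  sp <- RNifti::pixdim(img)[1:3]
  org <- tryCatch(as.numeric(RNifti::origin(img)), error = function(e) c(0, 0, 0))
  vox <- array(as.numeric(img), d)
  if (!clamp) {
    return(structure(list(voxels = vox, spacing = as.numeric(sp),
                          origin = org, phase = phase), class = "ct_volume"))
  }
  ct_volume(vox, spacing = sp, origin = org, phase = phase)
}

#' Write a CT volume, mask, or PRM label map to NIfTI
#'
#' @param vol a [ct_volume], [lung_mask] or [prm_map].
#' @param path output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  if (inherits(vol, "ct_volume")) {
    arr <- vol$voxels
    dt <- "double"
    sp <- vol$spacing
  } else if (inherits(vol, "lung_mask")) {
    arr <- array(as.integer(vol$voxels), dim(vol$voxels))
    dt <- "int16"
    sp <- vol$spacing
  } else if (inherits(vol, "prm_map")) {
    arr <- vol$labels
    dt <- "int16"
    sp <- vol$spacing
  } else stop("unsupported object: expected ct_volume, lung_mask or prm_map")
  attr(arr, "pixdim") <- sp
  img <- RNifti::asNifti(arr, datatype = dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

## 6-connected components of a logical array, via igraph.  Returns an
## integer array of component ids (0 = background).
.components3d <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  fg <- which(mask)
  if (length(fg) == 0L) return(array(0L, d))
  id <- integer(n)
  id[fg] <- seq_along(fg)
  edges <- vector("list", 3L)
  strides <- c(1L, d[1], d[1] * d[2])
  coord <- arrayInd(fg, d)
  for (ax in 1:3) {
    ok <- coord[, ax] < d[ax]
    nb <- fg[ok] + strides[ax]
    keep <- mask[nb]
    edges[[ax]] <- cbind(id[fg[ok][keep]], id[nb[keep]])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(e) > 0) g <- igraph::add_edges(g, t(e))
  comp <- igraph::components(g)$membership
  out <- array(0L, d)
  out[fg] <- comp
  out
}

#' Threshold-based lung mask
#'
#' Fallback lung segmentation for CT volumes: voxels below -320 HU are
#' candidate lung; connected components touching the x/y boundary faces
#' (exterior air) are discarded, the two largest remaining components are
#' kept, and internal holes are filled.
#'
#' @param vol inspiratory [ct_volume].
#' @param threshold candidate threshold in HU (default -320).
#' @return A [lung_mask].
#' @export
threshold_lung_mask <- function(vol, threshold = -320) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  cand <- vol$voxels < threshold
  comp <- .components3d(cand)
  ncomp <- max(comp)
  if (ncomp == 0L) stop("no lung found")
  touches <- unique(c(comp[1, , ], comp[d[1], , ], comp[, 1, ], comp[, d[2], ]))
  touches <- touches[touches > 0L]
  keep <- setdiff(seq_len(ncomp), touches)
  if (length(keep) == 0L) stop("no lung found")
  sizes <- tabulate(comp, nbins = ncomp)[keep]
  keep <- keep[order(sizes, decreasing = TRUE)][seq_len(min(2L, length(keep)))]
  mask <- array(comp %in% keep, d)
  if (!any(mask)) stop("no lung found")
  ## fill internal holes: background components with no boundary contact
  bgc <- .components3d(!mask)
  nb <- max(bgc)
  if (nb > 0L) {
    btouch <- unique(c(bgc[1, , ], bgc[d[1], , ], bgc[, 1, ], bgc[, d[2], ],
                       bgc[, , 1], bgc[, , d[3]]))
    btouch <- btouch[btouch > 0L]
    holes <- setdiff(seq_len(nb), btouch)
    if (length(holes) > 0L) mask[bgc %in% holes] <- TRUE
  }
  lung_mask(mask, spacing = vol$spacing)
}

PRM_COLORS <- c("#00000000",  # background: transparent
                "#00FF00FF",  # normal: green
                "#FFFF00FF",  # fSAD: yellow
                "#FF0000FF")  # emphysema: red

#' Write a PRM color overlay as a PNG slice stack
#'
#' Renders each axial slice of a PRM map with the conventional colour code:
#' green = normal parenchyma, yellow = fSAD, red = emphysema; background is
#' transparent.
#'
#' @param prm a [prm_map].
#' @param path output directory (created if missing) receiving
#'   `slice_###.png` files, one per axial slice.
#' @return Character vector of written file paths, invisibly.
#' @export
write_prm_overlay <- function(prm, path) {
  stopifnot(inherits(prm, "prm_map"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  d <- dim(prm$labels)
  rgba <- t(grDevices::col2rgb(PRM_COLORS, alpha = TRUE)) / 255
  files <- character(d[3])
  for (z in seq_len(d[3])) {
    sl <- prm$labels[, , z] + 1L
    img <- array(0, c(d[2], d[1], 4L))  # rows = y for conventional display
    for (ch in 1:4) img[, , ch] <- t(matrix(rgba[sl, ch], d[1], d[2]))
    files[z] <- file.path(path, sprintf("slice_%03d.png", z))
    png::writePNG(img, files[z])
  }
  invisible(files)
}
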