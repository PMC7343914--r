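# The virtual-cleaning step: erase the masked specimen to obtain a crust-only
# template series, then subtract the template from the untouched original so
# only the specimen remains.

#' Erase the masked region of a volume
#'
#' Voxels where the mask is true are set to `fill_hu`; every other voxel is
#' bit-identical to the input. The default fill (-2048 HU) lies below any
#' achievable HU, which makes the erased set exactly recoverable from
#' (original, template): the "coincidence set" of masked voxels that already
#' equalled the fill value is empty. Its size is reported as the attribute
#' `coincidence_count` and with a message when non-zero.
#'
#' @param volume a [ct_volume].
#' @param mask a congruent [binary_mask].
#' @param fill_hu HU value written into masked voxels.
#' @return A [ct_volume] tagged `"crust-template"`.
#' @export
erase_masked <- function(volume, mask, fill_hu = -2048) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "binary_mask"))
  if (!all(dim(volume$data) == dim(mask$data)))
    stop("volume and mask grids are not congruent")
  coincidence <- sum(volume$data[mask$data] == fill_hu)
  if (coincidence > 0)
    .sc_log("%d masked voxels already equal fill_hu = %g; they will not be recoverable by subtraction",
            coincidence, fill_hu)
  out <- volume$data
  out[mask$data] <- fill_hu
  res <- ct_volume(out, volume$spacing, volume$origin,
                   meta = utils::modifyList(volume$meta,
                                            list(derivation = "crust-template",
                                                 fill_hu = fill_hu)))
  attr(res, "coincidence_count") <- coincidence
  res
}

#' Subtract a crust template from the original series
#'
#' Realises the virtual-cleaning subtraction: wherever original and template
#' agree (outside the erased region) the output is `background_hu`; wherever
#' they differ the output keeps the original HU. The cleaned volume therefore
#' contains the specimen's original values inside the erased region and a
#' uniform background elsewhere. Masked voxels that happened to equal the
#' fill value (the coincidence set) are indistinguishable from background and
#' come out as background; use a fill below the HU minimum to make that set
#' empty.
#'
#' @param original the unaltered [ct_volume].
#' @param template the erased [ct_volume] from [erase_masked].
#' @param background_hu HU written outside the recovered region (air default).
#' @return A [ct_volume] tagged `"virtually-cleaned"`.
#' @export
subtract_template <- function(original, template, background_hu = -1024) {
  stopifnot(inherits(original, "ct_volume"), inherits(template, "ct_volume"))
  if (!all(dim(original$data) == dim(template$data)))
    stop("original and template grids are not congruent")
  diff_support <- original$data != template$data
  fills <- unique(template$data[diff_support])
  if (length(fills) > 1L)
    warning(sprintf(paste0("template is not consistent with a single erase: ",
                           "%d differing voxels carry %d distinct template ",
                           "values"), sum(diff_support), length(fills)))
  out <- array(background_hu, dim = dim(original$data))
  out[diff_support] <- original$data[diff_support]
  ct_volume(out, original$spacing, original$origin,
            meta = utils::modifyList(original$meta,
                                     list(derivation = "virtually-cleaned",
                                          background_hu = background_hu)))
}

#' Mask-applied preview of the specimen
#'
#' Convenience extraction mirroring a viewer's "compute volume" inspection:
#' original HU inside the mask, uniform background elsewhere. Identical math
#' to [erase_masked] followed by [subtract_template].
#'
#' @inheritParams erase_masked
#' @param background_hu HU outside the mask.
#' @return A [ct_volume] tagged `"masked-preview"`.
#' @export
compute_masked_preview <- function(volume, mask, background_hu = -1024) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "binary_mask"))
  if (!all(dim(volume$data) == dim(mask$data)))
    stop("volume and mask grids are not congruent")
  out <- array(background_hu, dim = dim(volume$data))
  out[mask$data] <- volume$data[mask$data]
  ct_volume(out, volume$spacing, volume$origin,
            meta = utils::modifyList(volume$meta,
                                     list(derivation = "masked-preview")))
}
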