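# Turn (image, mask) pairs into the four per-component images analyzed by
# the morphometric stack.

#' Extract one morphological component from an annotated image
#'
#' Returns an RGB raster in which every pixel outside the requested
#' component is exactly black `(0,0,0)`. An absent component yields an
#' empty-flagged result (`foreground_count = 0`) rather than an error.
#' Extracting a component from an already-extracted `component_image` is
#' the identity.
#'
#' @param image a `labeled_image`, a `component_image`, or an HxWx3 integer
#'   array (0-255).
#' @param mask integer matrix with codes 0-4; taken from the object when
#'   `image` is a `labeled_image`.
#' @param component `"T"`, `"TT"`, `"PC"` or `"S"` (or code 1-4).
#' @param subtype,parent_id metadata carried through when `image` is a bare
#'   array.
#' @return a `component_image`: list with `pixels`, `fg` (logical
#'   foreground matrix), `component`, `parent_id`, `subtype`,
#'   `foreground_count` and an `empty` flag.
#' @export
extract_component <- function(image, mask = NULL, component,
                              subtype = NA_character_,
                              parent_id = NA_character_) {
  comp_code <- as_component_code(component)
  comp_name <- names(bcc_components())[comp_code]
  if (inherits(image, "component_image")) {
    if (image$component != comp_name)
      stop("cannot extract component ", comp_name,
           " from a component image of ", image$component)
    return(image)
  }
  if (inherits(image, "labeled_image")) {
    mask <- mask %||% image$mask
    subtype <- image$subtype
    parent_id <- image$image_id
    image <- image$pixels
  }
  if (is.null(mask)) stop("a mask is required")
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("image and mask shapes differ")
  bad <- setdiff(unique(as.vector(mask)), 0:4)
  if (length(bad))
    stop("mask contains codes outside 0..4: ", paste(bad, collapse = ", "))
  fg <- mask == comp_code
  out <- image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[!fg] <- 0L
    out[, , ch] <- plane
  }
  structure(list(pixels = out, fg = fg, component = comp_name,
                 parent_id = parent_id, subtype = subtype,
                 foreground_count = sum(fg), empty = !any(fg)),
            class = "component_image")
}

#' Convert a component image to 8-bit grayscale
#'
#' Uses the ITU-R BT.601 luma: `gray = round(0.2989 R + 0.5870 G +
#' 0.1140 B)`, clipped to `[0, 255]`. Background pixels remain exactly 0.
#'
#' @param image a `component_image`.
#' @return a `gray_image`: list with `pixels` (integer matrix), `fg` and
#'   `provenance`.
#' @export
to_grayscale <- function(image) {
  stopifnot(inherits(image, "component_image"))
  g <- rgb_to_gray_int(image$pixels)
  g[!image$fg] <- 0L
  structure(list(pixels = g, fg = image$fg,
                 provenance = image$parent_id, component = image$component),
            class = "gray_image")
}

#' @export
print.component_image <- function(x, ...) {
  cat(sprintf("<component_image %s/%s> %d foreground px%s\n",
              x$parent_id, x$component, x$foreground_count,
              if (x$empty) " (empty)" else ""))
  invisible(x)
}
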