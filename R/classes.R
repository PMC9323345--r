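# Fixed code tables shared by every module.

#' Component and class code tables
#'
#' Mask codes are fixed: 0 = unannotated/background, 1 = tumor core (T),
#' 2 = touching tumor / peripheral palisade (TT), 3 = peritumoral cleft (PC),
#' 4 = stroma (S). The eight segmentation classes are the component crossed
#' with the subtype, in the order T-N, TT-N, PC-N, S-N, T-MN, TT-MN, PC-MN,
#' S-MN (codes 1..8; 0 stays reserved for unannotated pixels).
#'
#' @return `bcc_components()` returns the named component code vector;
#'   `bcc_classes()` the eight class names in code order.
#' @export
bcc_components <- function() c(T = 1L, TT = 2L, PC = 3L, S = 4L)

#' @rdname bcc_components
#' @export
bcc_classes <- function() {
  c("T-N", "TT-N", "PC-N", "S-N", "T-MN", "TT-MN", "PC-MN", "S-MN")
}

component_names <- function() names(bcc_components())

# component code + subtype -> 8-class code
class8_code <- function(mask, subtype) {
  stopifnot(subtype %in% c("N", "MN"))
  out <- mask
  tissue <- mask > 0L
  out[tissue] <- mask[tissue] + if (subtype == "MN") 4L else 0L
  out
}

as_component_code <- function(component) {
  codes <- bcc_components()
  if (is.character(component)) {
    if (!component %in% names(codes))
      stop("unknown component '", component, "'; expected one of ",
           paste(names(codes), collapse = ", "))
    codes[[component]]
  } else {
    if (!component %in% codes) stop("component code must be in 1..4")
    as.integer(component)
  }
}
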