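#' Trait order used throughout the package
#'
#' All trait vectors (EBVs, genetic means, responses, phenotypes) use the
#' fixed order milk (L), fat (kg), protein (kg), liveweight (kg).
#'
#' @return Character vector of the four trait names in canonical order.
#' @export
trait_names <- function() c("milk", "fat", "protein", "liveweight")

#' Construct a trait vector
#'
#' @param milk,fat,protein,liveweight Numeric scalars (litres, kg, kg, kg).
#' @return Named numeric vector in canonical trait order.
#' @export
trait_vector <- function(milk = 0, fat = 0, protein = 0, liveweight = 0) {
  x <- c(milk = milk, fat = fat, protein = protein, liveweight = liveweight)
  stopifnot(all(is.finite(x)))
  x
}

#' Breed order used throughout the package
#'
#' Holstein-Friesian (F), Jersey (J), Ayrshire (A).
#'
#' @return Character vector c("F", "J", "A").
#' @export
breed_names <- function() c("F", "J", "A")

# internal: coerce a length-4 numeric to a named trait vector, preserving order
as_trait_vector <- function(x) {
  stopifnot(is.numeric(x), length(x) == 4L)
  names(x) <- trait_names()
  x
}
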