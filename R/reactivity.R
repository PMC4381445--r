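#' @include outliers.R
NULL

## anhydro correction factors: polymer repeat unit (monomer minus water)
## over the free monomer, and the glucosyl moiety of sucrose
.ANHYDRO_GLUCOSE <- 162.14 / 180.16   # glucose  -> glucan
.ANHYDRO_XYLOSE  <- 132.11 / 150.13   # xylose   -> xylan
.SUCROSE_GLUCAN  <- 162.14 / 342.30   # sucrose  -> glucan equivalent

#' Carbohydrate release per gram of dry biomass
#'
#' Mass of monomeric sugar liberated by the combined dilute-acid
#' pretreatment and enzymatic hydrolysis assay, per unit dry biomass
#' loaded (the assay loads a 3.0 g sample in 30 mL of 1% sulfuric acid).
#'
#' @param massReleased grams of sugar released, >= 0
#' @param dryMass grams of dry biomass loaded, > 0
#' @return release in g/g
#' @examples
#' releasePerGram(0.72, 3.0)  # 0.24
#' @export
releasePerGram <- function(massReleased, dryMass) {
    if (any(dryMass <= 0))
        stop("dry mass must be positive")
    if (any(massReleased < 0))
        stop("released mass cannot be negative")
    massReleased / dryMass
}

#' Glucan yield (fraction of theoretical)
#'
#' Anhydro-corrected glucose release over the glucan-equivalent base:
#' \deqn{\frac{G.Release \cdot 162.14/180.16}
#'            {glucan + sucrose \cdot 162.14/342.30}}
#' Sucrose contributes only its glucosyl moiety; fructose is excluded.
#'
#' @param glucoseRelease glucose release, g per g dry biomass
#' @param glucanFrac glucan mass fraction of dry biomass
#' @param sucroseFrac sucrose mass fraction (default 0)
#' @return dimensionless yield; 1.0 = full theoretical conversion
#' @examples
#' glucanYield(0.24, 0.332)                      # ~0.65
#' glucanYield(0.332 * 180.16 / 162.14, 0.332)   # exactly 1
#' @export
glucanYield <- function(glucoseRelease, glucanFrac, sucroseFrac = 0) {
    base <- glucanFrac + sucroseFrac * .SUCROSE_GLUCAN
    if (any(base <= 0))
        stop("glucan (+ sucrose) base fraction must be positive")
    glucoseRelease * .ANHYDRO_GLUCOSE / base
}

#' Xylan yield (fraction of theoretical)
#'
#' Anhydro-corrected xylose release over the xylan mass fraction:
#' \deqn{\frac{X.Release \cdot 132.11/150.13}{xylan}}
#'
#' @param xyloseRelease xylose release, g per g dry biomass
#' @param xylanFrac xylan mass fraction of dry biomass, > 0
#' @return dimensionless yield
#' @export
xylanYield <- function(xyloseRelease, xylanFrac) {
    if (any(xylanFrac <= 0))
        stop("xylan fraction must be positive")
    xyloseRelease * .ANHYDRO_XYLOSE / xylanFrac
}

#' Combined (GX) release and yield
#'
#' `GX.Release` is the plain sum of the glucose and xylose releases.
#' `GX.Yield` is a pooled ratio -- the summed anhydro-corrected releases
#' over the summed carbohydrate bases -- rather than the sum of the two
#' component yields, so it stays on the same 0..1 scale as the
#' per-carbohydrate yields.
#'
#' @param glucoseRelease,xyloseRelease releases in g/g
#' @param glucanFrac,xylanFrac,sucroseFrac mass fractions of dry biomass
#' @return list with `gxRelease` and `gxYield`
#' @export
combinedSums <- function(glucoseRelease, xyloseRelease, glucanFrac,
                         xylanFrac, sucroseFrac = 0) {
    base <- glucanFrac + sucroseFrac * .SUCROSE_GLUCAN + xylanFrac
    if (any(base <= 0))
        stop("summed carbohydrate base must be positive")
    list(gxRelease = glucoseRelease + xyloseRelease,
         gxYield = (glucoseRelease * .ANHYDRO_GLUCOSE +
                    xyloseRelease * .ANHYDRO_XYLOSE) / base)
}

#' Build the six reactivity constituents from assay-level measurements
#'
#' Computes `G.Release`, `X.Release`, `GX.Release` (g/g) and `G.Yield`,
#' `X.Yield`, `GX.Yield` (fraction) for a set of samples.
#'
#' @param glucoseRelease,xyloseRelease per-sample releases in g/g
#' @param glucanFrac,xylanFrac per-sample mass fractions of dry biomass
#' @param sucroseFrac per-sample sucrose mass fraction (default 0)
#' @param sampleIDs sample identifiers
#' @return a [ConstituentTable-class] with the six reactivity columns
#' @export
reactivityTable <- function(glucoseRelease, xyloseRelease, glucanFrac,
                            xylanFrac, sucroseFrac = 0,
                            sampleIDs = names(glucoseRelease)) {
    n <- length(glucoseRelease)
    if (is.null(sampleIDs)) sampleIDs <- as.character(seq_len(n))
    sucroseFrac <- rep_len(sucroseFrac, n)
    gx <- combinedSums(glucoseRelease, xyloseRelease, glucanFrac,
                       xylanFrac, sucroseFrac)
    v <- cbind(G.Release = glucoseRelease,
               X.Release = xyloseRelease,
               GX.Release = gx$gxRelease,
               G.Yield = glucanYield(glucoseRelease, glucanFrac, sucroseFrac),
               X.Yield = xylanYield(xyloseRelease, xylanFrac),
               GX.Yield = gx$gxYield)
    ConstituentTable(v,
                     units = c(G.Release = "g_per_g", X.Release = "g_per_g",
                               GX.Release = "g_per_g", G.Yield = "fraction",
                               X.Yield = "fraction", GX.Yield = "fraction"),
                     sampleIDs = sampleIDs)
}
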