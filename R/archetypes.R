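# Six gluten network archetypes: lacunarity ranges, attribute direction
# arrows relative to a standard dough, and qualitative rheology.

NETWORK_TYPES <- c("cleaved", "rigid", "spread", "strengthened",
                   "particulate_dense", "particulate_loose")

# Direction arrows per attribute, relative to the corresponding standard
# dough. "--"/"++" are strong decreases/increases, "0" means unchanged.
ARCHETYPE_DIRECTIONS <- list(
  cleaved           = c(br = "--", pw = "+",  apl = "-",  epr = "++", ly = "-"),
  rigid             = c(br = "++", pw = "-",  apl = "++", epr = "--", ly = "-"),
  spread            = c(br = "++", pw = "-",  apl = "+",  epr = "-",  ly = "0"),
  strengthened      = c(br = "-",  pw = "+",  apl = "-",  epr = "+",  ly = "+"),
  particulate_dense = c(br = "-",  pw = "+",  apl = "--", epr = "++", ly = "+"),
  particulate_loose = c(br = "--", pw = "++", apl = "--", epr = "++", ly = "++")
)

# Lacunarity bins. Half-open convention (lo, hi], except cleaved which is
# closed at 0; the printed ranges 0-0.16 / 0.17-0.26 / 0.27-0.5 / >0.5
# leave sub-resolution gaps that the half-open convention closes.
LACUNARITY_RANGES <- list(
  cleaved           = c(0.00, 0.16),
  rigid             = c(0.16, 0.26),
  spread            = c(0.16, 0.26),
  strengthened      = c(0.16, 0.26),
  particulate_dense = c(0.26, 0.50),
  particulate_loose = c(0.50, Inf)
)

ARCHETYPE_RHEOLOGY <- c(
  cleaved           = "low_viscous",
  rigid             = "highly_viscous",
  spread            = "viscoelastic",
  strengthened      = "viscoelastic",
  particulate_dense = "highly_viscous",
  particulate_loose = "low_viscous"
)

ARCHETYPE_DESCRIPTIONS <- c(
  cleaved           = "Ruptured protein threads, short protein segments",
  rigid             = "Uniform, dense and continuous structure, highly branched",
  spread            = "Homogeneous, very branched, elongated and distributed protein threads",
  strengthened      = "Locally strengthened protein threads, continuous",
  particulate_dense = "Clustered agglomerates, densely arranged",
  particulate_loose = "Clustered agglomerates, widely scattered"
)

#' Gluten network archetype specification
#'
#' Returns the specification of one of the six gluten network types: its
#' lacunarity range, the direction of each microstructural attribute
#' relative to a standard dough (arrows collapsed to `--`, `-`, `0`, `+`,
#' `++`), its qualitative rheological character, and a one-line
#' description.
#'
#' @param network_type one of `"cleaved"`, `"rigid"`, `"spread"`,
#'   `"strengthened"`, `"particulate_dense"`, `"particulate_loose"`.
#' @return A list of class `archetype_spec` with elements `network_type`,
#'   `lacunarity_range`, `attribute_directions`, `rheology_summary` and
#'   `description`.
#' @seealso [network_archetypes()] for all six at once.
#' @examples
#' archetype_spec("cleaved")$attribute_directions
#' @export
archetype_spec <- function(network_type) {
  network_type <- match.arg(network_type, NETWORK_TYPES)
  structure(list(
    network_type         = network_type,
    lacunarity_range     = LACUNARITY_RANGES[[network_type]],
    attribute_directions = ARCHETYPE_DIRECTIONS[[network_type]],
    rheology_summary     = ARCHETYPE_RHEOLOGY[[network_type]],
    description          = ARCHETYPE_DESCRIPTIONS[[network_type]]
  ), class = "archetype_spec")
}

#' All six gluten network archetypes
#'
#' @return A named list of [archetype_spec()] objects, one per network
#'   type, in canonical order.
#' @export
network_archetypes <- function() {
  setNames(lapply(NETWORK_TYPES, archetype_spec), NETWORK_TYPES)
}

#' @export
print.archetype_spec <- function(x, ...) {
  cat(sprintf("<%s network>\n", gsub("_", ", ", x$network_type)))
  cat("  ", x$description, "\n", sep = "")
  rng <- x$lacunarity_range
  cat(sprintf("  lacunarity: (%.2f, %s]\n", rng[1],
              if (is.finite(rng[2])) sprintf("%.2f", rng[2]) else "Inf"))
  dirs <- x$attribute_directions
  cat("  directions vs standard: ",
      paste(names(dirs), dirs, sep = " ", collapse = ", "), "\n", sep = "")
  cat("  rheology: ", gsub("_", " ", x$rheology_summary), "\n", sep = "")
  invisible(x)
}

#' Direction arrow to multiplicative factor mapping
#'
#' The generator turns ordinal direction arrows into multiplicative
#' factors applied to the standard-dough attributes. The mapping is
#' configuration (the classification scheme gives only ordinal arrows).
#'
#' @param double_down,down,neutral,up,double_up factors for `--`, `-`,
#'   `0`, `+`, `++`.
#' @return Named numeric vector keyed by arrow symbol.
#' @export
direction_factors <- function(double_down = 0.5, down = 0.8, neutral = 1,
                              up = 1.3, double_up = 2) {
  c("--" = double_down, "-" = down, "0" = neutral, "+" = up,
    "++" = double_up)
}

# Collapse an arrow to its sign: "--","-" -> -1; "0" -> 0; "+","++" -> +1.
.arrow_sign <- function(arrow) {
  unname(c("--" = -1, "-" = -1, "0" = 0, "+" = 1, "++" = 1)[arrow])
}

# Clamp a lacunarity value into an archetype's (lo, hi] range.
.clamp_ly <- function(ly, range, eps = 1e-6) {
  pmin(pmax(ly, range[1] + eps), range[2])
}
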