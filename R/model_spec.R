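#' The five CMC regions in canonical order
#'
#' The Common Model of Cognition (CMC) maps five functional components onto
#' brain regions: motor cortex (MC, action), prefrontal cortex (PFC, working
#' memory), basal ganglia (BG, procedural memory), hippocampus and medial
#' temporal lobe (MTL, long-term memory), and sensory cortices (SENS,
#' perception). The index order MC = 1, PFC = 2, BG = 3, MTL = 4, SENS = 5 is
#' fixed; every matrix in the package uses it, with rows as targets and
#' columns as sources.
#'
#' @return Character vector of the five region labels in index order.
#' @export
cmc_regions <- function() {
  c("MC", "PFC", "BG", "MTL", "SENS")
}

# directed off-diagonal edges shared by both CMC variants, as
# (target, source) label pairs: three bidirectional cortico-cortical pairs
# plus PFC->MC and PFC->BG
cmc_shared_edges <- function() {
  rbind(
    c("MC",   "SENS"),
    c("SENS", "MC"),
    c("PFC",  "MTL"),
    c("MTL",  "PFC"),
    c("PFC",  "SENS"),
    c("SENS", "PFC"),
    c("MC",   "PFC"),
    c("BG",   "PFC")
  )
}

#' Build a CMC network specification
#'
#' Constructs the sparsity masks of one of the two CMC variants over the five
#' regions. Both variants share eight directed fixed connections
#' (SENS<->MC, MTL<->PFC, SENS<->PFC, PFC->MC, PFC->BG) and self-connections
#' on every region. The `direct` variant adds a fixed BG->PFC connection; the
#' `modulatory` variant replaces it with two second-order connections in
#' which the BG multiplicatively gate the MTL->PFC and SENS->PFC projections.
#' Every driver regressor enters every region, so the input mask is all ones.
#'
#' Masks are oriented row = target, column = source, matching the state
#' equation dy/dt = A y + C x + sum_i y_i D(i) y.
#'
#' @param variant `"modulatory"` or `"direct"`.
#' @param n_regressors Number of driver regressor columns (default 8, the
#'   four boxcar frequencies times two phases).
#' @return An object of class `cmc_spec` with elements `variant`, `regions`,
#'   `a_mask` (5 x 5 binary, diagonal all ones), `c_mask` (5 x K binary,
#'   all ones), and `d_triples` (m x 3 matrix of modulator, source, target
#'   region indices; zero rows for the direct variant).
#' @examples
#' spec <- cmc_spec("modulatory")
#' count_free_parameters(spec)
#' @export
cmc_spec <- function(variant = c("modulatory", "direct"), n_regressors = 8) {
  if (!is.character(variant) || !variant[1] %in% c("modulatory", "direct")) {
    stop("unknown CMC variant '", variant[1],
         "'; expected \"modulatory\" or \"direct\"", call. = FALSE)
  }
  variant <- match.arg(variant)
  stopifnot(is.numeric(n_regressors), length(n_regressors) == 1,
            n_regressors >= 1)
  n_regressors <- as.integer(n_regressors)

  regions <- cmc_regions()
  n <- length(regions)
  a_mask <- diag(1L, n)
  dimnames(a_mask) <- list(target = regions, source = regions)
  edges <- cmc_shared_edges()
  for (i in seq_len(nrow(edges))) {
    a_mask[edges[i, 1], edges[i, 2]] <- 1L
  }

  if (variant == "direct") {
    a_mask["PFC", "BG"] <- 1L
    d_triples <- matrix(integer(0), nrow = 0, ncol = 3)
  } else {
    d_triples <- rbind(
      c(match("BG", regions), match("MTL", regions), match("PFC", regions)),
      c(match("BG", regions), match("SENS", regions), match("PFC", regions))
    )
  }
  colnames(d_triples) <- c("modulator", "source", "target")

  c_mask <- matrix(1L, n, n_regressors,
                   dimnames = list(region = regions, input = NULL))

  structure(
    list(variant = variant, regions = regions, a_mask = a_mask,
         c_mask = c_mask, d_triples = d_triples),
    class = "cmc_spec"
  )
}

#' @export
print.cmc_spec <- function(x, ...) {
  cat("CMC network specification (", x$variant, " variant)\n", sep = "")
  cat("  regions:", paste(x$regions, collapse = ", "), "\n")
  off <- which(x$a_mask == 1 & row(x$a_mask) != col(x$a_mask))
  cat("  fixed connections:", length(off), "off-diagonal +",
      nrow(x$a_mask), "self\n")
  if (nrow(x$d_triples) > 0) {
    lab <- apply(x$d_triples, 1, function(tr) {
      paste0(x$regions[tr[1]], " modulates ", x$regions[tr[2]], "->",
             x$regions[tr[3]])
    })
    cat("  modulatory connections:\n")
    for (l in lab) cat("    ", l, "\n", sep = "")
  } else {
    cat("  modulatory connections: none (D fixed at 0)\n")
  }
  cat("  driver inputs:", ncol(x$c_mask), "(every input drives every region)\n")
  invisible(x)
}

#' Count the free parameters of a CMC specification
#'
#' Tallies the entries estimated under each mask: fixed (matrix A, including
#' the five always-present self-connections), input (matrix C), and
#' modulatory (matrix D). The two variants differ by exactly one parameter:
#' the modulatory variant trades the direct BG->PFC entry of A for two
#' gating entries of D.
#'
#' @param spec A [cmc_spec()] object.
#' @return A list with counts `fixed`, `input`, `modulatory`, `total`.
#' @export
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "cmc_spec"))
  fixed <- sum(spec$a_mask)
  input <- sum(spec$c_mask)
  modulatory <- nrow(spec$d_triples)
  list(fixed = fixed, input = input, modulatory = modulatory,
       total = fixed + input + modulatory)
}

#' Write or read a CMC specification as a JSON config
#'
#' The on-disk form stores the variant, region labels, the off-diagonal
#' fixed edges as label pairs, the modulatory triples as label triples, and
#' the number of driver inputs; masks are reconstructed on read.
#'
#' @param spec A [cmc_spec()] object.
#' @param path File path.
#' @return `read_cmc_spec` returns a `cmc_spec`; `write_cmc_spec` its path,
#'   invisibly.
#' @export
write_cmc_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cmc_spec"))
  off <- which(spec$a_mask == 1 & row(spec$a_mask) != col(spec$a_mask),
               arr.ind = TRUE)
  obj <- list(
    variant = spec$variant,
    regions = spec$regions,
    n_regressors = ncol(spec$c_mask),
    a_edges = data.frame(target = spec$regions[off[, 1]],
                         source = spec$regions[off[, 2]]),
    d_triples = if (nrow(spec$d_triples) > 0) {
      data.frame(modulator = spec$regions[spec$d_triples[, 1]],
                 source = spec$regions[spec$d_triples[, 2]],
                 target = spec$regions[spec$d_triples[, 3]])
    } else {
      data.frame(modulator = character(0), source = character(0),
                 target = character(0))
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cmc_spec
#' @export
read_cmc_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- cmc_spec(obj$variant, n_regressors = obj$n_regressors)
  # audit that the stored edge set matches the canonical variant
  off <- which(spec$a_mask == 1 & row(spec$a_mask) != col(spec$a_mask),
               arr.ind = TRUE)
  stored <- paste(obj$a_edges$target, obj$a_edges$source)
  canon <- paste(spec$regions[off[, 1]], spec$regions[off[, 2]])
  if (!setequal(stored, canon)) {
    stop("stored fixed-edge set does not match the '", obj$variant,
         "' variant", call. = FALSE)
  }
  spec
}
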