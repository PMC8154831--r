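#' Per-layer material parameters
#'
#' A \code{LayerParams} object collects every scalar constant of the biphasic
#' layer model in the fixed mm-N-s-MPa unit system (so MPa*mm^2 = N and
#' tensions integrate to N/mm):
#' \describe{
#'   \item{mu0 (MPa), q}{shear-stress scale and exponential stiffening factor
#'     of the solid strain energy.}
#'   \item{m1, m2}{isotropic matrix constants (distortional weight and
#'     volumetric exponent).}
#'   \item{m_fe, m_4e}{elastic fiber stiffness and nonlinearity exponent.}
#'   \item{m_fd, m_4d}{dissipative fiber branch stiffness and exponent.}
#'   \item{theta (degrees)}{out-of-plane elevation of the fiber directions.}
#'   \item{k_fd (mm^2 N^-1 s^-1)}{rate factor of the dissipative fiber
#'     branch.}
#'   \item{k0 (mm^4 N^-1 s^-1), kappa}{reference Darcy permeability and its
#'     deformation exponent.}
#'   \item{beta0 (MPa), beta1}{osmotic pressure at J = 1 and its volumetric
#'     exponent.}
#'   \item{phi_s_ref}{solid volume fraction in the (swollen) reference
#'     configuration.}
#'   \item{thickness (mm)}{reference thickness of the layer in a stack.}
#' }
#'
#' @param ... named scalar fields (see Details); unspecified fields must be
#'   supplied, there are no silent defaults.
#' @return object of class \code{LayerParams} (a validated named list).
#' @export
layer_params <- function(...) {
  p <- list(...)
  need <- c("mu0", "q", "m1", "m2", "m_fe", "m_4e", "m_fd", "m_4d",
            "theta", "k_fd", "k0", "kappa", "beta0", "beta1",
            "phi_s_ref", "thickness")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("layer_params: missing fields: ", paste(miss, collapse = ", "))
  unknown <- setdiff(names(p), need)
  if (length(unknown))
    stop("layer_params: unknown fields: ", paste(unknown, collapse = ", "))
  for (f in need) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("layer_params: field '", f, "' must be a finite numeric scalar")
  }
  if (p$mu0 <= 0) stop("layer_params: mu0 must be > 0")
  if (p$q <= 0) stop("layer_params: q must be > 0")
  if (p$k0 < 0) stop("layer_params: k0 must be >= 0")
  if (p$beta0 < 0) stop("layer_params: beta0 must be >= 0")
  if (p$thickness <= 0) stop("layer_params: thickness must be > 0")
  if (p$phi_s_ref <= 0 || p$phi_s_ref >= 1)
    stop("layer_params: phi_s_ref must lie in (0, 1)")
  if (p$theta < 0 || p$theta > 90)
    stop("layer_params: theta must lie in [0, 90] degrees")
  structure(p[need], class = "LayerParams")
}

#' @export
print.LayerParams <- function(x, ...) {
  cat("<LayerParams>  (units mm-N-s-MPa)\n")
  v <- unlist(x)
  print(signif(v, 6))
  invisible(x)
}

#' Built-in per-layer material table
#'
#' Returns the adopted material constants for the five tissues of the
#' multilayer skin model: epidermis (\code{Epi}), papillary dermis
#' (\code{PD}), reticular dermis (\code{RD}), hypodermis (\code{Hypo}) and
#' muscle (\code{Muscle}). Default thicknesses are Epi 0.1 mm, PD 0.2 mm,
#' RD 1.7 mm (so that a 2 mm ex vivo skin sample is Epi+PD+RD), Hypo 3 mm and
#' Muscle 2 mm.
#'
#' Several printed rows of the source table are typographically ambiguous
#' (run-together digit strings). The parsing adopted here assigns zero fiber
#' content to muscle (consistent with its zero fiber angle and zero fiber
#' rate factor) and satisfies the documented inter-layer trends: elastic
#' fiber stiffness and permeability increase from epidermis through papillary
#' to reticular dermis while the out-of-plane fiber angle decreases. The
#' resulting layer tangent moduli were checked against the reported
#' layer-wise linearized stiffness values; the alternative digit grouping
#' fails that check (see the methods vignette).
#'
#' @return named list of \code{\link{layer_params}} objects for
#'   \code{Epi, PD, RD, Hypo, Muscle}.
#' @export
builtin_table1 <- function() {
  list(
    Epi = layer_params(
      mu0 = 0.508e-2, q = 3.4, m1 = 0.2, m2 = 2,
      m_fe = 25, m_4e = 2.5, m_fd = 120, m_4d = 1.34,
      theta = 30, k_fd = 1.43e-2, k0 = 0.005, kappa = 2,
      beta0 = 2.19e-3, beta1 = 2, phi_s_ref = 0.3, thickness = 0.1),
    PD = layer_params(
      mu0 = 2.0608e-2, q = 3.4, m1 = 0.1, m2 = 1,
      m_fe = 110, m_4e = 1.415, m_fd = 250, m_4d = 1.34,
      theta = 10, k_fd = 1.43e-1, k0 = 0.05, kappa = 2,
      beta0 = 2.49e-3, beta1 = 2, phi_s_ref = 0.3, thickness = 0.2),
    RD = layer_params(
      mu0 = 0.668e-2, q = 3.4, m1 = 0.23, m2 = 1,
      m_fe = 240, m_4e = 1.34, m_fd = 1150, m_4d = 1.34,
      theta = 7, k_fd = 1.43e-2, k0 = 5, kappa = 2,
      beta0 = 2.49e-3, beta1 = 2, phi_s_ref = 0.3, thickness = 1.7),
    Hypo = layer_params(
      mu0 = 2e-4, q = 1.4, m1 = 0.05, m2 = 0.1,
      m_fe = 50, m_4e = 1.4, m_fd = 50, m_4d = 1.4,
      theta = 10, k_fd = 5.43, k0 = 15, kappa = 2,
      beta0 = 2.49e-4, beta1 = 2, phi_s_ref = 0.3, thickness = 3),
    Muscle = layer_params(
      mu0 = 10.668e-2, q = 3.4, m1 = 0.1725, m2 = 1,
      m_fe = 0, m_4e = 0, m_fd = 0, m_4d = 0,
      theta = 0, k_fd = 0, k0 = 0.5, kappa = 2,
      beta0 = 2.49e-3, beta1 = 2, phi_s_ref = 0.3, thickness = 2)
  )
}

#' Ordered stack of skin layers
#'
#' @param layers named list of \code{\link{layer_params}}, ordered from the
#'   top (epidermis) downwards.
#' @return object of class \code{LayerStack} with elements \code{layers} and
#'   \code{total_thickness} (mm).
#' @export
layer_stack <- function(layers) {
  if (!length(layers) || is.null(names(layers)) || any(names(layers) == ""))
    stop("layer_stack: 'layers' must be a non-empty named list")
  if (anyDuplicated(names(layers)))
    stop("layer_stack: layer names must be unique")
  for (nm in names(layers))
    if (!inherits(layers[[nm]], "LayerParams"))
      stop("layer_stack: layer '", nm, "' is not a LayerParams object")
  structure(list(
    layers = layers,
    total_thickness = sum(vapply(layers, `[[`, 0, "thickness"))
  ), class = "LayerStack")
}

#' @export
print.LayerStack <- function(x, ...) {
  cat("<LayerStack> ", length(x$layers), "layer(s), total thickness",
      format(x$total_thickness), "mm (top to bottom)\n")
  for (nm in names(x$layers))
    cat(sprintf("  %-8s %g mm\n", nm, x$layers[[nm]]$thickness))
  invisible(x)
}

#' Default ex vivo skin stack (Epi/PD/RD)
#'
#' Epidermis 0.1 mm, papillary dermis 0.2 mm and reticular dermis making up
#' the remainder of the sample thickness (default sample 2 mm, so RD 1.7 mm).
#'
#' @param sample_thickness total sample thickness in mm (> 0.3).
#' @return a \code{\link{layer_stack}}.
#' @export
skin_stack <- function(sample_thickness = 2) {
  if (sample_thickness <= 0.3)
    stop("skin_stack: sample_thickness must exceed Epi+PD = 0.3 mm")
  tab <- builtin_table1()
  tab$RD$thickness <- sample_thickness - tab$Epi$thickness - tab$PD$thickness
  layer_stack(tab[c("Epi", "PD", "RD")])
}

#' Read a layer stack from a YAML configuration file
#'
#' The file holds a top-level \code{layers:} sequence; each entry has a
#' \code{name:} (one of the built-in materials, or any name if all fields are
#' given) and optional field overrides, e.g.
#' \preformatted{
#' layers:
#'   - name: Epi
#'     thickness: 0.1
#'   - name: PD
#'     thickness: 0.2
#'   - name: RD
#'     thickness: 1.7
#' }
#' Unknown field keys and non-positive thicknesses are rejected.
#'
#' @param path configuration file path.
#' @return a \code{\link{layer_stack}}.
#' @export
load_stack <- function(path) {
  if (!file.exists(path)) stop("load_stack: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layers)) stop("load_stack: config has no 'layers' section")
  tab <- builtin_table1()
  layers <- list()
  for (entry in cfg$layers) {
    nm <- entry$name
    if (is.null(nm)) stop("load_stack: layer entry without 'name'")
    base <- if (nm %in% names(tab)) unclass(tab[[nm]]) else list()
    over <- entry[setdiff(names(entry), "name")]
    # numbers may arrive as full-precision strings (see write_stack)
    over <- lapply(over, function(v)
      if (is.character(v)) as.numeric(v) else v)
    bad <- setdiff(names(over), names(tab$Epi))
    if (length(bad))
      stop("load_stack: unknown key(s) for layer '", nm, "': ",
           paste(bad, collapse = ", "))
    base[names(over)] <- over
    layers[[nm]] <- do.call(layer_params, base)
  }
  layer_stack(layers)
}

#' Write a layer stack to a YAML configuration file
#'
#' All numeric fields are written explicitly so that
#' \code{load_stack(write_stack(x, f))} reproduces them exactly.
#'
#' @param stack a \code{\link{layer_stack}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "LayerStack"))
  entries <- lapply(names(stack$layers), function(nm) {
    c(list(name = nm), lapply(unclass(stack$layers[[nm]]), identity))
  })
  # full precision round trip: serialise numbers via format with 17 digits
  yaml::write_yaml(
    list(layers = entries), path,
    precision = 17L, handlers = list(numeric = function(x) {
      res <- format(x, digits = 17, scientific = TRUE)
      structure(res, class = "verbatim")
    }))
  invisible(path)
}

#' Export the built-in material table as CSV
#'
#' One row per parameter, one column per material, mirroring the layout of
#' the printed table.
#'
#' @param path output CSV path.
#' @return the data frame written, invisibly.
#' @export
export_table1_csv <- function(path) {
  tab <- builtin_table1()
  fields <- setdiff(names(tab$Epi), "thickness")
  df <- data.frame(
    parameter = fields,
    do.call(cbind, lapply(tab, function(p) unlist(p[fields]))),
    check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
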