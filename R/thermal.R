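#' Thermal parameters of the storage reactor
#'
#' Conduction, evaporation and capacitance constants of the single-node
#' energy balance. Defaults are the calibrated reactor values: thermal
#' conductivity 10.1 W/m/K, heat-flux area 0.6 m2, characteristic length
#' 0.08 m and stainless-steel volume 0.01 m3. The stainless constants
#' (7750 kg/m3, 480 J/kg/K) and the latent heat of vaporization
#' (2257 kJ/kg) are literature values.
#'
#' @param k_cond Thermal conductivity, W/m/K.
#' @param area Heat-flux area, m2 (shared by conduction and convection).
#' @param length Characteristic length, m.
#' @param v_ss Stainless-steel volume contributing to capacitance, m3 (`>= 0`).
#' @param rho_ss Stainless-steel density, kg/m3.
#' @param c_ss Stainless-steel specific heat, J/kg/K.
#' @param h_vap Latent heat of vaporization, kJ/kg.
#' @param h_conv_override Optional fixed convective coefficient, W/m2/K;
#'   when set it replaces the Nusselt-correlation estimate (the experimental
#'   value for these reactors is 2.2 W/m2/K).
#'
#' @return An object of class `thermal_params`.
#' @export
thermal_params <- function(k_cond = 10.1, area = 0.6, length = 0.08,
                           v_ss = 0.01, rho_ss = 7750, c_ss = 480,
                           h_vap = 2257, h_conv_override = NULL) {
  pos <- c(k_cond = k_cond, area = area, length = length, rho_ss = rho_ss,
           c_ss = c_ss, h_vap = h_vap)
  if (any(pos <= 0))
    stop("thermal parameters must be strictly positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "), call. = FALSE)
  if (v_ss < 0) stop("v_ss must be >= 0", call. = FALSE)
  if (!is.null(h_conv_override) && h_conv_override < 0)
    stop("h_conv_override must be >= 0", call. = FALSE)
  structure(list(k_cond = k_cond, area = area, length = length, v_ss = v_ss,
                 rho_ss = rho_ss, c_ss = c_ss, h_vap = h_vap,
                 h_conv_override = h_conv_override),
            class = "thermal_params")
}

#' Film properties of the aeration air
#'
#' Fixed near-300 K film values used by the Nusselt-number correlation; the
#' convective term is small for these reactors, so temperature dependence of
#' the air properties is neglected.
#'
#' @param k_air Air thermal conductivity, W/m/K.
#' @param nu Kinematic viscosity, m2/s.
#' @param pr Prandtl number, dimensionless.
#' @param rho_air Air density, kg/m3.
#' @param cp_air Air specific heat, J/kg/K.
#'
#' @return An object of class `air_properties`.
#' @export
air_properties <- function(k_air = 0.0263, nu = 1.568e-5, pr = 0.707,
                           rho_air = 1.1614, cp_air = 1007) {
  vals <- c(k_air = k_air, nu = nu, pr = pr, rho_air = rho_air,
            cp_air = cp_air)
  if (any(vals <= 0))
    stop("air properties must be strictly positive", call. = FALSE)
  structure(as.list(vals), class = "air_properties")
}

#' Water-jacket feedback controller model
#'
#' The circulating water jacket is programmed to track the internal biomass
#' temperature with a -0.5 K offset once the closed-loop controller engages
#' (internal temperature above 20 degrees C); below the activation threshold
#' the jacket holds its floor temperature. This internal model is used only
#' when no measured jacket series is supplied.
#'
#' @param offset Jacket tracking offset, K (negative).
#' @param activation_threshold Internal temperature above which the
#'   controller engages, degrees C.
#' @param floor_temperature Jacket temperature while inactive, degrees C.
#'
#' @return An object of class `jacket_controller`.
#' @export
jacket_controller <- function(offset = -0.5, activation_threshold = 20,
                              floor_temperature = 20) {
  if (offset >= 0) stop("jacket offset must be negative", call. = FALSE)
  structure(list(offset = offset, activation_threshold = activation_threshold,
                 floor_temperature = floor_temperature),
            class = "jacket_controller")
}

#' Jacket temperature given the biomass temperature
#'
#' @param t_stover Biomass temperature(s), degrees C. Vectorized.
#' @param ctrl A [jacket_controller()].
#'
#' @return Jacket temperature(s), degrees C.
#' @examples
#' jacket_temperature(30, jacket_controller())  # 29.5
#' jacket_temperature(15, jacket_controller())  # 20 (controller inactive)
#' @export
jacket_temperature <- function(t_stover, ctrl = jacket_controller()) {
  stopifnot(inherits(ctrl, "jacket_controller"))
  ifelse(t_stover > ctrl$activation_threshold,
         t_stover + ctrl$offset, ctrl$floor_temperature)
}

#' Conductive heat flow into the biomass node
#'
#' `Q_k = (k_cond / length) * area * (t_jacket - t_stover)`; positive values
#' warm the biomass. Antisymmetric under swapping the two temperatures.
#'
#' @param t_stover Biomass temperature, degrees C.
#' @param t_jacket Jacket temperature, degrees C.
#' @param p A [thermal_params()] object.
#'
#' @return Heat flow, W (positive = entering the biomass).
#' @export
conductive_heat <- function(t_stover, t_jacket, p = thermal_params()) {
  stopifnot(inherits(p, "thermal_params"))
  (p$k_cond / p$length) * p$area * (t_jacket - t_stover)
}

#' Convective heat-transfer coefficient from a flat-plate correlation
#'
#' Turbulent flat-plate Nusselt correlation `Nu = 0.0296 Re^0.8 Pr^(1/3)`
#' with `Re = u L / nu`, giving `h = Nu k_air / L`. Returns 0 at zero
#' velocity.
#'
#' @param air An [air_properties()] object.
#' @param u Air velocity over the biomass, m/s (`>= 0`).
#' @param length Characteristic length, m.
#'
#' @return Heat-transfer coefficient, W/m2/K.
#' @export
convective_coefficient <- function(air = air_properties(), u, length = 0.08) {
  stopifnot(inherits(air, "air_properties"))
  if (any(u < 0)) stop("air velocity must be >= 0", call. = FALSE)
  re <- u * length / air$nu
  nu_x <- 0.0296 * re^0.8 * air$pr^(1 / 3)
  nu_x * air$k_air / length
}

#' Convective heat flow into the biomass node
#'
#' `Q_h = h * area * (t_ambient - t_stover)`; positive values warm the
#' biomass.
#'
#' @param t_stover Biomass temperature, degrees C.
#' @param t_ambient Ambient air temperature, degrees C.
#' @param h Heat-transfer coefficient, W/m2/K (`>= 0`).
#' @param area Heat-flux area, m2.
#'
#' @return Heat flow, W.
#' @export
convective_heat <- function(t_stover, t_ambient, h, area) {
  if (any(h < 0)) stop("h must be >= 0", call. = FALSE)
  h * area * (t_ambient - t_stover)
}

#' Evaporative heat loss
#'
#' `E = -h_vap * rate`; always non-positive, since condensate leaving the
#' reactor carries latent heat with it.
#'
#' @param condensate_rate Water removal rate, kg/s (`>= 0`).
#' @param h_vap Latent heat of vaporization, kJ/kg.
#'
#' @return Heat flow, W (always `<= 0`).
#' @export
evaporation_heat <- function(condensate_rate, h_vap = 2257) {
  if (any(condensate_rate < 0))
    stop("condensate_rate must be >= 0", call. = FALSE)
  -h_vap * 1000 * condensate_rate
}

#' Water-balance evaporation rate of the linear drying schedule
#'
#' When no measured condensate series is available, the evaporation rate is
#' taken as the constant rate implied by the drying schedule: the wet-basis
#' water mass `dm * m / (1 - m)` lost between the initial and final moisture
#' contents, spread uniformly over the storage duration.
#'
#' @param moisture A [moisture_model()].
#' @param dm_g Loading dry matter, g.
#'
#' @return Constant water removal rate, kg/s (`>= 0`).
#' @export
default_evaporation_rate <- function(moisture, dm_g) {
  stopifnot(inherits(moisture, "moisture_model"), dm_g > 0)
  if (moisture$m_initial >= 1 || moisture$m_final >= 1)
    stop("wet-basis moisture must be < 1", call. = FALSE)
  water_g <- function(m) dm_g * m / (1 - m)
  lost <- water_g(moisture$m_initial) - water_g(moisture$m_final)
  max(lost, 0) / 1000 / (moisture$duration_days * 86400)
}

#' Specific heat of dry biomass
#'
#' Linear correlation for dry woody biomass, `c_dry = 0.1031 + 0.00386 T`
#' with `T` in kelvin, returning kJ/kg/K. At room temperature this gives
#' ~1.25 kJ/kg/K, consistent with literature dry-wood and dry corn stover
#' ranges.
#'
#' @param t_k Absolute temperature, K (`> 0`).
#'
#' @return Specific heat, kJ/kg/K.
#' @export
specific_heat_dry <- function(t_k) {
  if (any(t_k <= 0)) stop("absolute temperature must be > 0 K", call. = FALSE)
  0.1031 + 0.00386 * t_k
}

#' Specific heat of wet biomass
#'
#' Moist-wood correction accounting for the energy absorbed by wood-water
#' bonds:
#' `c_wet = (c_dry + 4.19 m) / (1 + m) + (0.02355 T - 1.32 m - 6.191) m`
#' with `T` in kelvin and `m` the wet-basis moisture fraction. Reduces to
#' the dry correlation at `m = 0`.
#'
#' @param t_k Absolute temperature, K.
#' @param m Moisture fraction in `[0, 1)`.
#'
#' @return Specific heat, kJ/kg/K.
#' @export
specific_heat_wet <- function(t_k, m) {
  if (any(m < 0 | m >= 1)) stop("moisture must lie in [0, 1)", call. = FALSE)
  (specific_heat_dry(t_k) + 4.19 * m) / (1 + m) +
    (0.02355 * t_k - 1.32 * m - 6.191) * m
}

#' Biomass contribution to the thermal capacitance
#'
#' Two bases are supported. `loaded_mass` (default) uses the wet mass
#' actually loaded, `dm / (1 - m)`; `density_volume` uses a literature bulk
#' density times the reactor volume (the literal density-times-volume
#' definition, which for these reactors implies far more mass than was
#' loaded).
#'
#' @param loading_dry_matter_g Loading dry matter, g (`> 0`).
#' @param capacitance_mode `"loaded_mass"` or `"density_volume"`.
#' @param bulk_density Bulk density for `density_volume` mode, kg/m3.
#' @param volume Reactor volume, m3.
#'
#' @return An object of class `biomass_properties`.
#' @export
biomass_properties <- function(loading_dry_matter_g,
                               capacitance_mode = c("loaded_mass",
                                                    "density_volume"),
                               bulk_density = 942, volume = 0.074) {
  capacitance_mode <- match.arg(capacitance_mode)
  if (loading_dry_matter_g <= 0)
    stop("loading_dry_matter_g must be > 0", call. = FALSE)
  if (volume <= 0) stop("volume must be > 0", call. = FALSE)
  structure(list(loading_dry_matter_g = loading_dry_matter_g,
                 capacitance_mode = capacitance_mode,
                 bulk_density = bulk_density, volume = volume),
            class = "biomass_properties")
}

#' Lumped thermal capacitance of the loaded reactor
#'
#' Biomass term (wet mass times wet specific heat) plus the stainless-steel
#' term `rho_ss * v_ss * c_ss`.
#'
#' @param bio A [biomass_properties()] object.
#' @param p A [thermal_params()] object.
#' @param t_k Absolute temperature, K.
#' @param m Wet-basis moisture fraction.
#'
#' @return Thermal capacitance, J/K.
#' @export
thermal_capacitance <- function(bio, p, t_k, m) {
  stopifnot(inherits(bio, "biomass_properties"), inherits(p, "thermal_params"))
  mass_kg <- switch(bio$capacitance_mode,
    loaded_mass = (bio$loading_dry_matter_g / 1000) / (1 - m),
    density_volume = bio$bulk_density * bio$volume)
  mass_kg * specific_heat_wet(t_k, m) * 1000 + p$rho_ss * p$v_ss * p$c_ss
}

#' Net heat balance of the biomass node
#'
#' Plain signed sum of the microbial, conductive, convective and evaporative
#' terms, all expressed relative to the biomass node (positive = warming).
#'
#' @param q_m,q_k,q_h,e Heat flows, W.
#'
#' @return Net heat flow, W.
#' @export
heat_balance <- function(q_m, q_k, q_h, e) q_m + q_k + q_h + e

#' Temperature derivative of the lumped node
#'
#' @param q_th Net heat flow, W.
#' @param c_th Thermal capacitance, J/K (`> 0`).
#'
#' @return Temperature derivative, K/s.
#' @export
temperature_derivative <- function(q_th, c_th) {
  if (any(c_th <= 0))
    stop("thermal capacitance must be > 0 (empty reactor?)", call. = FALSE)
  q_th / c_th
}
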