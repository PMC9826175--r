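# Reference parameter sets used across tests
cp_spec <- reference_spec("chung_pfost")
halsey_spec <- reference_spec("halsey")
henderson_spec <- reference_spec("henderson")
oswin_spec <- reference_spec("oswin")
all_specs <- list(chung_pfost = cp_spec, halsey = halsey_spec,
                  henderson = henderson_spec, oswin = oswin_spec)

std_temps <- seq(25, 65, by = 10)
emc_grid_std <- seq(0.05, 0.30, by = 0.01)

# central-difference oracle for d ln(ERH)/dT, h in kelvin
num_dlnerh <- function(spec, emc, temp_c, h = 1e-4) {
  (log(predict_erh(spec, emc, temp_c + h)) -
     log(predict_erh(spec, emc, temp_c - h))) / (2 * h)
}
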