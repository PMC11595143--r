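# shared internal constants; this file collates first

PARAM_NAMES <- c("ka", "k_endog", "Vc_F", "CL_F", "Vp_F", "Q_F", "C0",
                 "fm1", "C0_m1", "V_m1", "CL_m1", "fm2", "C0_m2", "V_m2",
                 "CL_m2", "C0_m3", "V_m3", "CL_m3")
FRACTION_PARAMS <- c("fm1", "fm2")

# default fixed (non-estimated) parameter set of the final model
DEFAULT_FIXED <- c("ka", "k_endog", "Vp_F", "Q_F", "fm1", "fm2")

PV_IDX <- stats::setNames(seq_along(PARAM_NAMES), PARAM_NAMES)

`%||%` <- function(a, b) if (is.null(a)) b else a
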