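# Versioned radiobiological model parameter file.
# Each value carries a "source" citation key. Values marked approximate are
# transcriptions consistent with the cited fits, not printed constants, and
# should be replaced with exact published coefficients before clinical use.
version: 1
alpha_beta:                 # Gy, per tissue, used for EQD2 conversion
  tumor: 10.0               # source: NSCLC convention (Mehta 2001; Fowler 2004)
  lung: 1.3                 # source: Borst 2010 radiation-pneumonitis fit
  chest_wall: 3.0           # source: late-responding normal tissue convention
tcp:
  martel:                   # logistic dose-response, 30-month local control
    d50: 84.5               # Gy EQD2; source: Martel 1997 NSCLC fit
    gamma50: 1.5            # source: Martel 1997
  fenwick:                  # covariate logistic in dose summary + tumor size
    c0: 0.0                 # intercept; approximate, source: Fenwick 2009 family
    c1: 0.03                # per Gy EQD2; approximate
    c2: -0.5                # per cm equivalent-sphere diameter; approximate
    size_unit: cm
  webb_nahum:               # Poisson kill, population-averaged radiosensitivity
    alpha_mean: 0.30        # Gy^-1; source: Carmichael cell-line average
    alpha_sigma: 0.1        # Gy^-1; source: Carmichael cell-line average
    rho: 1.0e+8             # clonogens per cm^3; source: Lindblom
  eud:                      # SF2-based EUD fed into a logistic response
    alpha: 0.30             # Gy^-1 (SF2 = exp(-2 alpha)); source: Carmichael
    tcd50: 51.9             # Gy; source: Okunieff pooled dose-response
    gamma50: 0.83           # source: Okunieff
  nitin:                    # logistic fit to SBRT local-control series
    d50: 60.0               # Gy EQD2; approximate, source: Ohri SBRT pooled fit
    gamma50: 1.0            # approximate
ntcp:
  lkb:                      # EUD-based Lyman-Kutcher-Burman, radiation pneumonitis
    td50: 30.8              # Gy EQD2; source: Seppenwoolde 2003
    m: 0.37                 # source: Seppenwoolde 2003
    n_volume: 0.99          # source: Seppenwoolde 2003 (near mean-lung-dose)
  fenwick_lung:             # logistic in mean lung EQD2 dose
    c0: -3.87               # approximate, source: mean-lung-dose pneumonitis fits
    c1: 0.126               # per Gy
meud:                       # chest-wall modified EUD on hottest subvolume
  a_exponent: 1.0           # power-mean exponent
  weighting: moderate       # none | moderate | strong
  weight_exponents:         # dose-weight exponent b in w_i = D_i^b
    none: 0.0
    moderate: 1.0           # approximate preset
    strong: 2.0
  subvolume_cc: 100.0       # hottest chest-wall subvolume analysed
pipeline:
  dose_summary_mode: mean   # mean | sf2_eud -- summary fed to logistic TCP models
  normality_alpha: 0.05     # Shapiro-Wilk gate for paired t-test vs Wilcoxon
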