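# Substrate-partition anchor points digitized from:
#   Romijn JA, Coyle EF, Gastaldelli A, Sidossis LS, Horowitz JF, Endert E,
#   Wolfe RR (1993). Regulation of endogenous fat and carbohydrate metabolism
#   in relation to exercise intensity and duration. Am J Physiol 265
#   (Endocrinol Metab 28): E380-E391.
# One-time digitization of the published stacked substrate-oxidation figures
# (trained subjects, 30-minute time point); values are approximate reads of
# the plotted bars, not printed numbers.
# Columns:
#   intensity : exercise intensity as a fraction of VO2max (dimensionless)
#   f_cho     : fraction of aerobic energy expenditure from carbohydrate,
#               defined as x_cho / (x_cho + x_fat) (holds exactly by column
#               construction)
#   x_fat     : whole-body fat oxidation rate, cal kg^-1 min^-1
#   x_cho     : whole-body carbohydrate oxidation rate, cal kg^-1 min^-1
#   se_fat    : standard error of x_fat, cal kg^-1 min^-1
#   se_cho    : standard error of x_cho, cal kg^-1 min^-1
intensity	f_cho	x_fat	x_cho	se_fat	se_cho
0.25	0.28	57.6	22.4	2.5	1.3
0.65	0.46	112.32	95.68	6	6
0.85	0.67	89.76	182.24	7	9
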