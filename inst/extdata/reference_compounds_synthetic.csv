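# Synthetic reference compound set for efflux screening.
# LogD values (octanol/water, pH 7.4) are literature-typical; the transfer
# constants are SYNTHETIC, placed on (passive) or below (efflux) the
# representative passive-diffusion line log10 K_in(mL/s/g) = 0.45*LogD - 1.60.
# This table is editable configuration, not experimental ground truth.
name,logd,kin_ul_s_g,known_class
antipyrine,0.38,41.69,passive
caffeine,-0.07,18.62,passive
diazepam,2.58,478.6,passive
phenytoin,2.08,154.9,passive
ethanol,-0.31,21.88,passive
nicotine,0.99,61.66,passive
thiourea,-1.02,10.96,passive
propranolol,1.20,123.0,passive
quinidine,2.41,1.905,efflux
loperamide,3.35,1.288,efflux
digoxin,1.26,1.479,efflux
cimetidine,0.35,1.148,efflux
verapamil,2.60,9.333,efflux
R123,1.51,0.12,efflux
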