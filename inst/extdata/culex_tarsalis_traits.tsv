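# Default trait-curve configuration for the relative mosquito-abundance
# index, in the style of published Culex tarsalis thermal-performance fits.
# Units: EFD eggs female^-1 day^-1; pEA probability; MDR day^-1; lf days.
# Briere: c*T*(T-Tmin)*sqrt(Tmax-T); quadratic: c*(T-Tmin)*(Tmax-T);
# both are exactly 0 outside [Tmin, Tmax]. Edit freely; structure is
# validated, values are not.
trait	form	c	Tmin	Tmax
EFD	briere	0.00856	14.6	34.6
pEA	quadratic	0.00599	13.6	38.3
MDR	briere	0.0000786	11.4	39.2
lf	quadratic	0.148	9.2	37.7
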