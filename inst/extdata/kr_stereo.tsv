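# Stereochemical conventions applied by reductive domains, editable without
# code changes. beta_stereo is the SMILES tag written on the beta-carbon when
# a ketoreductase of that type reduces the beta-ketone; alpha_stereo is the
# tag written on the alpha-carbon when it carries exactly one substituent.
# "." means no descriptor is assigned. C1 performs no reduction at all; C2
# epimerizes the alpha-substituent only. The ER row gives the alpha
# descriptor restored after enoylreduction.
kr_type	beta_stereo	alpha_stereo
A1	@	@@
A2	@	@
B1	@@	@@
B2	@@	@
C1	.	.
C2	.	@
U	.	.
ER	.	@@
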