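# Example 3D "pattern A" relationships (organisms 2 and 3 co-present when organism 1 is present, co-excluded when absent)
# identified in HMP anterior nares samples at genus level, population threshold m = 0.1.
# Octant proportions p_ijk are reported at two-decimal precision; scores are the sums over cells 000, 111, 010, 001.
organism1	organism2	organism3	score	p000	p001	p010	p011	p100	p101	p110	p111
[G] Actinomyces	[G] Rothia	[G] Neisseria	0.94	0.48	0.12	0.18	0.05	0.00	0.00	0.02	0.16
[F] Ruminococcaceae	[G] Bacteroides	[F] Lachnospiraceae	0.94	0.54	0.12	0.17	0.03	0.02	0.00	0.00	0.11
[G] Faecalibacterium	[G] Bacteroides	[F] Lachnospiraceae	0.94	0.57	0.12	0.16	0.04	0.00	0.00	0.02	0.10
[G] Oscillospira	[G] Bacteroides	[F] Lachnospiraceae	0.94	0.60	0.12	0.12	0.03	0.01	0.01	0.02	0.10
[G] Oscillospira	[F] Lachnospiraceae	[G] Faecalibacterium	0.94	0.57	0.10	0.17	0.04	0.01	0.02	0.00	0.10
[G] Neisseria	[G] Rothia	[G] Prevotella	0.94	0.56	0.15	0.12	0.02	0.01	0.01	0.02	0.11
[G] Neisseria	[G] Rothia	[G] Veillonella	0.94	0.48	0.23	0.10	0.04	0.01	0.01	0.00	0.13
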