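PWY_GLYCOLYSIS_synthetic	synthetic example set	P0001	P0002	P0003	P0004	P0005	P0006
PWY_FATTY_ACID_OXIDATION_synthetic	synthetic example set	P0007	P0008	P0009	P0010	P0011
PWY_OXPHOS_synthetic	synthetic example set	P0012	P0013	P0014	P0015	P0016	P0017	P0018
PWY_KETONE_METABOLISM_synthetic	synthetic example set	P0019	P0020	P0021	P0022
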