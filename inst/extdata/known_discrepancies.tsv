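compound	quantity	reported	computed	note
5a	esi_2m_na_mz	763	773	reported [2M+Na]+ inconsistent with 2*M+Na from the compound formula; likely transcription error in the source characterization data
6y	esi_fragment_mz	368.8798	NA	reported in-source fragment [M-C4H7NO]+ mass not consistent with any neutral-loss sub-formula of C23H22BrN3O2
6e	esi_adduct_type	[M+Cl+Na]+	NA	nonstandard chloride-sodium double adduct reported instead of [M+H]+/[M+Na]+; not modelled by the supported adduct set
5n	docking_score_bche	-7.681/-7.861	NA	source discussion prints two different BChE docking scores for the same compound; both recorded, neither reproducible without the commercial engine
6h	anal_calcd_mass	403.48	403.48	duplicated calculated-analysis statement in the source gives the average mass where sibling entries give monoisotopic; average mass matches, flagged for convention only
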