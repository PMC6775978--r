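set_name	member	ko_id	rule	theta	expectation
wood_ljungdahl	fwdA		fraction	0.5	present
wood_ljungdahl	fwdB		fraction	0.5	present
wood_ljungdahl	fwdC		fraction	0.5	present
wood_ljungdahl	fwdD		fraction	0.5	present
wood_ljungdahl	fwdE		fraction	0.5	present
wood_ljungdahl	fwdF		fraction	0.5	present
wood_ljungdahl	fwdG		fraction	0.5	present
wood_ljungdahl	ftr	K00672	fraction	0.5	present
wood_ljungdahl	mch	K01499	fraction	0.5	present
wood_ljungdahl	mtd	K00319	fraction	0.5	present
wood_ljungdahl	mer	K00320	fraction	0.5	present
wood_ljungdahl	mtrA	K00577	fraction	0.5	present
wood_ljungdahl	hdrB	K03389	fraction	0.5	present
wood_ljungdahl	hdrC	K03390	fraction	0.5	present
wood_ljungdahl	hdrD	K08264	fraction	0.5	present
sulfate_reduction	sat	K00958	all		present
sulfate_reduction	aprA	K00394	all		present
sulfate_reduction	aprB	K00395	all		present
sulfate_reduction	dsrA	K11180	all		present
sulfate_reduction	dsrB	K11181	all		present
nitrate_reduction	napA	K02567	any		present
nitrate_reduction	napD		any		present
nitrate_reduction	napG		any		present
nitrate_reduction	napH		any		present
nitrate_reduction	narG	K00370	any		present
nitrate_reduction	narH	K00371	any		present
nitrate_reduction	narI	K00374	any		present
nitrate_reduction	narJ	K00373	any		present
co_oxidation	cooS	K00198	any		present
co_oxidation	cooC		any		present
codh_acs	cdhA	K00192	any		present
codh_acs	cdhB	K00195	any		present
codh_acs	cdhC	K00193	any		present
codh_acs	cdhD	K00194	any		present
codh_acs	cdhE	K00197	any		present
nife_hydrogenase	hypA	K04651	fraction	0.5	present
nife_hydrogenase	hypB	K04652	fraction	0.5	present
nife_hydrogenase	hypC	K04653	fraction	0.5	present
nife_hydrogenase	hypD	K04654	fraction	0.5	present
nife_hydrogenase	hypE	K04655	fraction	0.5	present
nife_hydrogenase	hypF	K04656	fraction	0.5	present
glycolysis	pmm		all		present
glycolysis	gpi	K01810	all		present
glycolysis	fba	K01624	all		present
glycolysis	fbp	K03841	all		present
glycolysis	gap	K00134	all		present
glycolysis	pgk	K00927	all		present
glycolysis	pgm	K01834	all		present
glycolysis	eno	K01689	all		present
glycolysis	pk	K00873	all		present
rubisco	rbcL	K01601	any		present
methanogenesis	mcrA	K00399	any		absent
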