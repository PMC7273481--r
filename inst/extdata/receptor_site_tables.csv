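table,status,group,count
ER_by_site_class,positive,distant,36
ER_by_site_class,positive,regional,198
ER_by_site_class,negative,distant,28
ER_by_site_class,negative,regional,110
PR_by_site_class,positive,distant,12
PR_by_site_class,positive,regional,52
PR_by_site_class,negative,distant,40
PR_by_site_class,negative,regional,29
HER2_by_site_class,positive,distant,23
HER2_by_site_class,positive,regional,103
HER2_by_site_class,equivocal,distant,11
HER2_by_site_class,equivocal,regional,95
HER2_by_site_class,negative,distant,24
HER2_by_site_class,negative,regional,112
ER_by_major_site,positive,bone,8
ER_by_major_site,positive,liver,4
ER_by_major_site,positive,lung,1
ER_by_major_site,negative,bone,4
ER_by_major_site,negative,liver,4
ER_by_major_site,negative,lung,1
PR_by_major_site,positive,bone,4
PR_by_major_site,positive,liver,2
PR_by_major_site,positive,lung,1
PR_by_major_site,negative,bone,7
PR_by_major_site,negative,liver,5
PR_by_major_site,negative,lung,5
HER2_by_major_site,positive,bone,3
HER2_by_major_site,positive,liver,3
HER2_by_major_site,positive,lung,6
HER2_by_major_site,equivocal,bone,3
HER2_by_major_site,equivocal,liver,0
HER2_by_major_site,equivocal,lung,5
HER2_by_major_site,negative,bone,4
HER2_by_major_site,negative,liver,1
HER2_by_major_site,negative,lung,0
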