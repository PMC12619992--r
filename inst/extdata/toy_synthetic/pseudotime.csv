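cell_id,pseudotime
cell001,0.914806043496355
cell002,0.937075413297862
cell003,0.286139534786344
cell004,0.830447626067325
cell005,0.641745518893003
cell006,0.519095949130133
cell007,0.736588314641267
cell008,0.13466659723781
cell009,0.656992290401831
cell010,0.705064784036949
cell011,0.45774177624844
cell012,0.719112251652405
cell013,0.934672247152776
cell014,0.255428824340925
cell015,0.462292822543532
cell016,0.940014522755519
cell017,0.978226428385824
cell018,0.117487361654639
cell019,0.474997081561014
cell020,0.560332746244967
cell021,0.904031387297437
cell022,0.138710167724639
cell023,0.988891728920862
cell024,0.946668232558295
cell025,0.0824375580996275
cell026,0.514211784349754
cell027,0.390203467104584
cell028,0.905738130910322
cell029,0.446969628101215
cell030,0.836004259996116
cell031,0.737595617771149
cell032,0.811055141268298
cell033,0.388108282815665
cell034,0.685169729404151
cell035,0.00394833879545331
cell036,0.832916080253199
cell037,0.00733414688147604
cell038,0.207658972823992
cell039,0.906601407798007
cell040,0.611778643447906
cell041,0.379559240536764
cell042,0.435771584976465
cell043,0.0374310328625143
cell044,0.973539913771674
cell045,0.431751248892397
cell046,0.957576596643776
cell047,0.887754905503243
cell048,0.639978769468144
cell049,0.970966610359028
cell050,0.618838207330555
cell051,0.333427211269736
cell052,0.346748248208314
cell053,0.39848541142419
cell054,0.784692775690928
cell055,0.038936491124332
cell056,0.748795386170968
cell057,0.67727683018893
cell058,0.171264330390841
cell059,0.261087963823229
cell060,0.514412934659049
cell061,0.67560727451928
cell062,0.982817197917029
cell063,0.759544267551973
cell064,0.566488424083218
cell065,0.849689718568698
cell066,0.18947393540293
cell067,0.271286614704877
cell068,0.828158485237509
cell069,0.693204820388928
cell070,0.240544739644974
cell071,0.0429887960199267
cell072,0.140479094116017
cell073,0.21638541505672
cell074,0.479398564202711
cell075,0.197410342283547
cell076,0.719355837674811
cell077,0.00788473873399198
cell078,0.375489964615554
cell079,0.514407708309591
cell080,0.00157055421732366
cell081,0.581604002509266
cell082,0.157905208179727
cell083,0.359028305858374
cell084,0.645631878403947
cell085,0.775823362637311
cell086,0.563646841561422
cell087,0.233703398611397
cell088,0.0899805163498968
cell089,0.0856120649259537
cell090,0.305218369467184
cell091,0.667426514672115
cell092,0.000238896580412984
cell093,0.208569956943393
cell094,0.933034127345309
cell095,0.925644748611376
cell096,0.734094301005825
cell097,0.333071983419359
cell098,0.515063329832628
cell099,0.743974646320567
cell100,0.619159240042791
cell101,0.62624534452334
cell102,0.217157698236406
cell103,0.216567310970277
cell104,0.388945028651506
cell105,0.942455691983923
cell106,0.962608013767749
cell107,0.73985527921468
cell108,0.73324590572156
cell109,0.535761289997026
cell110,0.00227296608500183
cell111,0.608937452547252
cell112,0.836801559431478
cell113,0.751522562699392
cell114,0.452731572557241
cell115,0.535789993824437
cell116,0.53737669531256
cell117,0.00138084357604384
cell118,0.355665953829885
cell119,0.612133090151474
cell120,0.828942130552605
cell121,0.356721999356523
cell122,0.410635125823319
cell123,0.573475898941979
cell124,0.589678303571418
cell125,0.719657292356715
cell126,0.394973045215011
cell127,0.919203929137439
cell128,0.962570293573663
cell129,0.233523525530472
cell130,0.724497599992901
cell131,0.903634525137022
cell132,0.603474084753543
cell133,0.631507298909128
cell134,0.937385849654675
cell135,0.850482750684023
cell136,0.579820899059996
cell137,0.821403923910111
cell138,0.113718609092757
cell139,0.764507758663967
cell140,0.623613457195461
cell141,0.148446606704965
cell142,0.0802644665818661
cell143,0.464069551322609
cell144,0.779368161456659
cell145,0.73352795955725
cell146,0.817230444401503
cell147,0.170162481255829
cell148,0.94472032552585
cell149,0.293623841367662
cell150,0.149072052445263
cell151,0.719378591282293
cell152,0.324085952481255
cell153,0.778809498529881
cell154,0.394441001815721
cell155,0.67859286791645
cell156,0.775825042743236
cell157,0.187869044020772
cell158,0.0290858189109713
cell159,0.135713797062635
cell160,0.680164178134874
cell161,0.9348229537718
cell162,0.550494084367529
cell163,0.601766235427931
cell164,0.19699448812753
cell165,0.535236610565335
cell166,0.179555739276111
cell167,0.451886494411156
cell168,0.317053351784125
cell169,0.116174670401961
cell170,0.186102156760171
cell171,0.729730096645653
cell172,0.41187207121402
cell173,0.414049681741744
cell174,0.480310129001737
cell175,0.427494465606287
cell176,0.136490360135213
cell177,0.824679406359792
cell178,0.592304242542014
cell179,0.794396977638826
cell180,0.769032425712794
cell181,0.918056417256594
cell182,0.862629777053371
cell183,0.316975237801671
cell184,0.259260575985536
cell185,0.74226645193994
cell186,0.74736111680977
cell187,0.917904034024104
cell188,0.793191209202632
cell189,0.133329618256539
cell190,0.287749752169475
cell191,0.194676143815741
cell192,0.784109382657334
cell193,0.128872161731124
cell194,0.129089283524081
cell195,0.0722531112842262
cell196,0.0531294834800065
cell197,0.531874436419457
cell198,0.112308241659775
cell199,0.74318771972321
cell200,0.731315477285534
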