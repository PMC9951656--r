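id,sex,age_years
HH001,male,0
HH002,male,0
HH003,male,0
HH004,male,0
HH005,male,0
HH006,male,0
HH007,male,0
HH008,male,0
HH009,male,0
HH010,male,0
HH011,male,0
HH012,male,0
HH013,male,0
HH014,male,0
HH015,male,0
HH016,male,0
HH017,male,0
HH018,male,0
HH019,male,0
HH020,male,0
HH021,male,0
HH022,male,0
HH023,male,0
HH024,male,0
HH025,male,0
HH026,male,0
HH027,male,0
HH028,male,0
HH029,male,0
HH030,male,0
HH031,male,0
HH032,male,0
HH033,male,0
HH034,male,0
HH035,male,0
HH036,male,0
HH037,male,0
HH038,male,0
HH039,male,0
HH040,male,0
HH041,male,0
HH042,male,0
HH043,male,0
HH044,female,0
HH045,female,0
HH046,female,0
HH047,female,0
HH048,female,0
HH049,female,0
HH050,female,0
HH051,female,0
HH052,female,0
HH053,female,0
HH054,female,0
HH055,female,0
HH056,female,0
HH057,female,0
HH058,female,0
HH059,female,0
HH060,female,0
HH061,female,0
HH062,female,0
HH063,female,0
HH064,female,0
HH065,female,0
HH066,female,0
HH067,female,0
HH068,female,0
HH069,female,0
HH070,female,0
HH071,female,0
HH072,female,0
HH073,female,0
HH074,female,0
HH075,female,0
HH076,female,0
HH077,female,0
HH078,female,0
HH079,female,0
HH080,female,0
HH081,female,0
HH082,female,0
HH083,unknown,0
HH084,unknown,0
HH085,unknown,0
HH086,unknown,0
HH087,unknown,0
HH088,unknown,0
HH089,unknown,0
HH090,unknown,0
HH091,unknown,0
HH092,unknown,0
HH093,unknown,0
HH094,unknown,0
HH095,unknown,0
HH096,unknown,0
HH097,unknown,0
HH098,unknown,0
HH099,unknown,0
HH100,unknown,0
HH101,unknown,0
HH102,unknown,0
HH103,unknown,0
HH104,unknown,0
HH105,unknown,0
HH106,unknown,0
HH107,unknown,0
HH108,unknown,0
HH109,unknown,0
HH110,male,1
HH111,male,1
HH112,male,1
HH113,male,1
HH114,male,1
HH115,male,1
HH116,male,1
HH117,male,1
HH118,male,1
HH119,male,1
HH120,male,1
HH121,male,1
HH122,male,1
HH123,male,1
HH124,male,1
HH125,male,1
HH126,male,1
HH127,male,1
HH128,male,1
HH129,male,1
HH130,male,1
HH131,male,1
HH132,male,1
HH133,male,1
HH134,male,1
HH135,male,1
HH136,male,1
HH137,male,1
HH138,male,1
HH139,male,1
HH140,male,1
HH141,male,1
HH142,male,1
HH143,male,1
HH144,male,1
HH145,male,1
HH146,male,1
HH147,male,1
HH148,male,1
HH149,male,1
HH150,male,1
HH151,male,1
HH152,male,1
HH153,male,1
HH154,male,1
HH155,male,1
HH156,male,1
HH157,male,1
HH158,male,1
HH159,male,1
HH160,male,1
HH161,male,1
HH162,male,1
HH163,male,1
HH164,female,1
HH165,female,1
HH166,female,1
HH167,female,1
HH168,female,1
HH169,female,1
HH170,female,1
HH171,female,1
HH172,female,1
HH173,female,1
HH174,female,1
HH175,female,1
HH176,female,1
HH177,female,1
HH178,female,1
HH179,female,1
HH180,female,1
HH181,female,1
HH182,female,1
HH183,female,1
HH184,female,1
HH185,unknown,1
HH186,unknown,1
HH187,unknown,1
HH188,unknown,1
HH189,unknown,1
HH190,unknown,1
HH191,unknown,1
HH192,unknown,1
HH193,unknown,1
HH194,unknown,1
HH195,unknown,1
HH196,unknown,1
HH197,unknown,1
HH198,unknown,1
HH199,unknown,1
HH200,unknown,1
HH201,unknown,1
HH202,unknown,1
HH203,unknown,1
HH204,unknown,1
HH205,unknown,1
HH206,unknown,1
HH207,unknown,1
HH208,unknown,1
HH209,unknown,1
HH210,unknown,1
HH211,unknown,1
HH212,unknown,1
HH213,unknown,1
HH214,unknown,1
HH215,unknown,1
HH216,unknown,1
HH217,unknown,1
HH218,unknown,1
HH219,unknown,1
HH220,unknown,1
HH221,unknown,1
HH222,unknown,1
HH223,unknown,1
HH224,unknown,1
HH225,male,2
HH226,male,2
HH227,male,2
HH228,male,2
HH229,male,2
HH230,male,2
HH231,male,2
HH232,male,2
HH233,male,2
HH234,male,2
HH235,male,2
HH236,male,2
HH237,male,2
HH238,male,2
HH239,male,2
HH240,male,2
HH241,male,2
HH242,male,2
HH243,male,2
HH244,male,2
HH245,male,2
HH246,male,2
HH247,male,2
HH248,female,2
HH249,female,2
HH250,female,2
HH251,female,2
HH252,female,2
HH253,female,2
HH254,female,2
HH255,female,2
HH256,female,2
HH257,female,2
HH258,female,2
HH259,female,2
HH260,female,2
HH261,female,2
HH262,female,2
HH263,unknown,2
HH264,unknown,2
HH265,unknown,2
HH266,unknown,2
HH267,unknown,2
HH268,unknown,2
HH269,unknown,2
HH270,unknown,2
HH271,unknown,2
HH272,unknown,2
HH273,unknown,2
HH274,unknown,2
HH275,unknown,2
HH276,unknown,2
HH277,unknown,2
HH278,unknown,2
HH279,male,3
HH280,male,3
HH281,male,3
HH282,male,3
HH283,male,3
HH284,male,3
HH285,male,3
HH286,male,3
HH287,male,3
HH288,male,3
HH289,male,3
HH290,male,3
HH291,male,3
HH292,male,3
HH293,male,3
HH294,male,3
HH295,male,3
HH296,male,3
HH297,male,3
HH298,male,3
HH299,male,3
HH300,male,3
HH301,male,3
HH302,male,3
HH303,male,3
HH304,male,3
HH305,male,3
HH306,male,3
HH307,male,3
HH308,female,3
HH309,female,3
HH310,female,3
HH311,female,3
HH312,female,3
HH313,female,3
HH314,female,3
HH315,female,3
HH316,female,3
HH317,female,3
HH318,female,3
HH319,female,3
HH320,female,3
HH321,female,3
HH322,female,3
HH323,female,3
HH324,female,3
HH325,female,3
HH326,unknown,3
HH327,unknown,3
HH328,unknown,3
HH329,unknown,3
HH330,unknown,3
HH331,unknown,3
HH332,male,4
HH333,male,4
HH334,male,4
HH335,male,4
HH336,male,4
HH337,male,4
HH338,female,4
HH339,female,4
HH340,female,4
HH341,female,4
HH342,female,4
HH343,female,4
HH344,female,4
HH345,female,4
HH346,female,4
HH347,unknown,4
HH348,unknown,4
HH349,unknown,4
HH350,unknown,4
HH351,unknown,4
HH352,unknown,4
HH353,unknown,4
HH354,male,5
HH355,male,5
HH356,male,5
HH357,male,5
HH358,male,5
HH359,male,5
HH360,male,5
HH361,female,5
HH362,female,5
HH363,female,5
HH364,female,5
HH365,female,5
HH366,female,5
HH367,unknown,5
HH368,unknown,5
HH369,male,6
HH370,male,6
HH371,male,6
HH372,male,6
HH373,male,6
HH374,male,6
HH375,male,6
HH376,male,6
HH377,female,6
HH378,unknown,6
HH379,unknown,6
HH380,male,9
HH381,male,9
HH382,male,10
HH383,male,10
HH384,unknown,10
HH385,unknown,10
HH386,male,11
HH387,male,13
HH388,male,16
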