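year,variable,category,cm,cc,ci,ca,tfr
2006,religion,Catholic,0.756688,0.81124,0.72359,1.0,6.8
2006,religion,Protestant,0.688570,0.76740,0.74156,1.0,6.0
2006,religion,Moslem,0.723129,0.71102,0.75700,1.0,6.0
2006,religion,Other,0.677555,0.78402,0.73206,1.0,5.9
2006,region,Kampala,0.532694,0.52907,0.81400,1.0,3.5
2006,region,Central,0.680401,0.66009,0.76805,1.0,5.3
2006,region,Eastern,0.776696,0.79588,0.74267,1.0,7.0
2006,region,Northern,0.773491,0.90037,0.69493,1.0,7.4
2006,region,Western,0.749218,0.77022,0.73475,1.0,6.5
2006,residence,Rural,0.761407,0.81240,0.72966,1.0,6.9
2006,residence,Urban,0.562910,0.56882,0.79239,1.0,3.9
2006,wealth_quintile,Poorest,0.815166,0.92263,0.71200,1.0,8.2
2006,wealth_quintile,Poor,0.767808,0.85478,0.71023,1.0,7.1
2006,wealth_quintile,Middle,0.739220,0.81104,0.71968,1.0,6.6
2006,wealth_quintile,Richer,0.759015,0.73921,0.75614,1.0,6.5
2006,wealth_quintile,Richest,0.577128,0.53849,0.79618,1.0,3.8
2006,education,None,0.830933,0.89279,0.70547,1.0,8.0
2006,education,Primary,0.748226,0.78791,0.73233,1.0,6.6
2006,education,Secondary+,0.611473,0.56484,0.79904,1.0,4.2
2006,total,Uganda,0.722717,0.78179,0.73502,1.0,6.4
2011,religion,Catholic,0.739750,0.75710,0.75103,1.0,6.4
2011,religion,Protestant,0.686338,0.68546,0.77042,1.0,5.5
2011,religion,Moslem,0.765173,0.70558,0.77160,1.0,6.4
2011,religion,Other,0.796222,0.65513,0.75729,1.0,6.0
2011,region,Kampala,0.568926,0.54316,0.83333,1.0,3.9
2011,region,Central,0.718897,0.64366,0.79491,1.0,5.6
2011,region,Eastern,0.758391,0.74057,0.77042,1.0,6.6
2011,region,Northern,0.723603,0.84672,0.72150,1.0,6.8
2011,region,Western,0.721989,0.68546,0.75358,1.0,5.7
2011,residence,Rural,0.780517,0.76701,0.74822,1.0,6.9
2011,residence,Urban,0.592744,0.57047,0.81136,1.0,4.2
2011,wealth_quintile,Poorest,0.821068,0.89191,0.73233,1.0,8.2
2011,wealth_quintile,Poor,0.797797,0.78723,0.73665,1.0,7.1
2011,wealth_quintile,Middle,0.749112,0.71637,0.73719,1.0,6.1
2011,wealth_quintile,Richer,0.741234,0.66709,0.77131,1.0,5.8
2011,wealth_quintile,Richest,0.584853,0.54365,0.81934,1.0,4.0
2011,education,None,0.820628,0.87626,0.72595,1.0,8.0
2011,education,Primary,0.765763,0.72988,0.75047,1.0,6.4
2011,education,Secondary+,0.598991,0.56241,0.82203,1.0,4.2
2011,total,Uganda,0.724311,0.71870,0.76190,1.0,6.1
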