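index,event_id,name,category,direction,unit
1,sprint_100m,100m sprint,sprint,minimize,seconds
2,sprint_200m,200m sprint,sprint,minimize,seconds
3,run_400m,400m running,middle/long running,minimize,seconds
4,run_800m,800m running,middle/long running,minimize,seconds
5,run_3000m,3000m running,middle/long running,minimize,seconds
6,run_10000m,"10,000m running",middle/long running,minimize,seconds
7,marathon,marathon,marathon,minimize,seconds
8,back_100m,100m backstroke,swim,minimize,seconds
9,back_200m,200m backstroke,swim,minimize,seconds
10,breast_100m,100m breaststroke,swim,minimize,seconds
11,breast_200m,200m breaststroke,swim,minimize,seconds
12,fly_100m,100m butterfly,swim,minimize,seconds
13,fly_200m,200m butterfly,swim,minimize,seconds
14,free_50m,50m freestyle,swim,minimize,seconds
15,free_100m,100m freestyle,swim,minimize,seconds
16,free_200m,200m freestyle,swim,minimize,seconds
17,free_400m,400m freestyle,swim,minimize,seconds
18,free_800m,800m freestyle,swim,minimize,seconds
19,medley_200m,200m medley,swim,minimize,seconds
20,medley_400m,400m medley,swim,minimize,seconds
21,hurdles_400m,400m hurdles,hurdles,minimize,seconds
22,long_jump,long jump,jump,maximize,meters
23,high_jump,high jump,jump,maximize,meters
24,triple_jump,triple jump,jump,maximize,meters
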